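# Rad-score construction: LASSO-penalized Cox regression over the texture
# features, tuned by stratified 10-fold cross-validation repeated many times,
# with the per-repetition full-data coefficients averaged elementwise.

#' Z-score a raw feature matrix
#'
#' Columns are centered and scaled by their population standard deviation
#' (divisor n), the convention of penalized-regression software.
#' Zero-variance columns cannot carry prognostic information and are
#' retained as zeros but flagged ineligible for selection.
#'
#' @param x Numeric matrix or data frame of raw features (rows = patients).
#' @return A `rad_feature_matrix`: list with `x` (standardized matrix),
#'   `center`, `scale` and logical `zero_var`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    stop("missing feature values for rows: ", paste(bad, collapse = ", "))
  }
  if (nrow(x) < 30L) stop("need at least 30 patients, got ", nrow(x))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- sqrt(colMeans(xc^2))         # population SD, exact 0 for constants
  zero_var <- scale == 0
  scale_safe <- ifelse(zero_var, 1, scale)
  xs <- sweep(xc, 2, scale_safe, "/")
  xs[, zero_var] <- 0
  structure(list(x = xs, center = center, scale = scale_safe,
                 zero_var = zero_var),
            class = "rad_feature_matrix")
}

# Fold labels stratified on event status so every fold keeps events even at
# an ~11% event rate.
stratified_folds <- function(event, nfolds) {
  foldid <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    foldid[idx] <- sample(rep(seq_len(nfolds), length.out = length(idx)))
  }
  foldid
}

#' Fit the LASSO-Cox penalty path
#'
#' The L1-penalized Cox partial-likelihood path (Breslow ties) over a
#' log-spaced penalty grid, by default 100 values from `lambda_max` (the
#' smallest penalty shrinking every coefficient to zero) down to
#' `0.01 * lambda_max`.
#'
#' @inheritParams cv_lasso_cox_once
#' @param lambda.min.ratio Smallest penalty as a fraction of `lambda_max`.
#' @return The `glmnet` fit object.
#' @export
lasso_cox_path <- function(fm, time, event, lambda.min.ratio = 0.01,
                           thresh = 1e-5) {
  stopifnot(inherits(fm, "rad_feature_matrix"))
  exclude <- which(fm$zero_var)
  glmnet::glmnet(
    fm$x, survival::Surv(time, event), family = "cox",
    nlambda = 100L, lambda.min.ratio = lambda.min.ratio,
    standardize = FALSE, thresh = thresh,
    exclude = if (length(exclude)) exclude else NULL
  )
}

#' One repetition of cross-validated LASSO-Cox
#'
#' Fits the L1-penalized Cox partial likelihood (Breslow ties) over a
#' log-spaced grid of 100 penalties from `lambda_max` down to
#' `0.01 * lambda_max`, picks the penalty minimizing the 10-fold
#' cross-validated partial-likelihood deviance (minimum criterion), and
#' returns the full-data coefficients at that penalty.
#'
#' @param fm A `rad_feature_matrix` from [standardize()].
#' @param time,event Survival time (months) and event indicator (0/1).
#' @param fold_seed Integer seed for the stratified fold assignment.
#' @param nfolds Number of CV folds (default 10).
#' @param thresh Coordinate-descent convergence threshold (default 1e-5).
#' @return List with `lambda_min`, `coefficients` (full p-vector, zeros
#'   included) and `n_selected`.
#' @export
cv_lasso_cox_once <- function(fm, time, event, fold_seed, nfolds = 10L,
                              thresh = 1e-5) {
  stopifnot(inherits(fm, "rad_feature_matrix"))
  if (sum(event == 1) < 10L) {
    stop("insufficient events for cross-validated selection: ",
         sum(event == 1))
  }
  y <- survival::Surv(time, event)
  exclude <- which(fm$zero_var)
  foldid <- with_seed(fold_seed, stratified_folds(event, nfolds))
  cv <- glmnet::cv.glmnet(
    fm$x, y, family = "cox", foldid = foldid,
    nlambda = 100L, lambda.min.ratio = 0.01,
    standardize = FALSE, thresh = thresh,
    exclude = if (length(exclude)) exclude else NULL
  )
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  list(lambda_min = cv$lambda.min, coefficients = beta,
       n_selected = sum(beta != 0))
}

#' Build a radiomics signature by repeated cross-validated selection
#'
#' Runs [cv_lasso_cox_once()] with seeds `base_seed .. base_seed +
#' n_repeats - 1`, averages the per-repetition coefficient vectors
#' elementwise, sets the signature size K to the rounded mean number of
#' selected features, and keeps the K features with largest absolute
#' averaged coefficient (ties broken by manifest order). The averaged
#' coefficients of those features are the signature weights.
#'
#' @inheritParams cv_lasso_cox_once
#' @param n_repeats Number of cross-validation repetitions (default 100).
#' @param base_seed Integer; repetition r uses fold seed `base_seed + r - 1`.
#' @param K Optional override of the signature size.
#' @return A `rad_signature`: list with `K`, `selected`, `weights`,
#'   `center`, `scale`, `mean_n_selected`, `n_repeats`, `base_seed`.
#' @export
repeated_cv_select <- function(fm, time, event, n_repeats = 100L, base_seed,
                               K = NULL, nfolds = 10L, thresh = 1e-5) {
  stopifnot(inherits(fm, "rad_feature_matrix"))
  p <- ncol(fm$x)
  coef_sum <- numeric(p)
  n_sel <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fit <- cv_lasso_cox_once(fm, time, event, fold_seed = base_seed + r - 1L,
                             nfolds = nfolds, thresh = thresh)
    coef_sum <- coef_sum + fit$coefficients
    n_sel[r] <- fit$n_selected
  }
  avg <- coef_sum / n_repeats
  K_auto <- as.integer(round(mean(n_sel)))
  K <- if (is.null(K)) K_auto else as.integer(K)
  if (K < 1L) {
    stop("no signal: all cross-validation repetitions selected 0 features")
  }
  ord <- order(-abs(avg), seq_len(p))      # ties -> manifest order
  sel <- sort(ord[seq_len(K)])
  nm <- colnames(fm$x)
  if (is.null(nm)) nm <- paste0("f", seq_len(p))
  structure(
    list(K = K, selected = nm[sel], weights = setNames(avg[sel], nm[sel]),
         center = setNames(fm$center[sel], nm[sel]),
         scale = setNames(fm$scale[sel], nm[sel]),
         mean_n_selected = mean(n_sel), n_repeats = n_repeats,
         base_seed = base_seed),
    class = "rad_signature"
  )
}

#' @export
print.rad_signature <- function(x, ...) {
  cat("Radiomics signature:", x$K, "features",
      sprintf("(mean selected per repetition: %.1f over %d repetitions)\n",
              x$mean_n_selected, x$n_repeats))
  top <- head(x$weights[order(-abs(x$weights))], 5L)
  for (nm in names(top)) cat(sprintf("  %-40s %+.4f\n", nm, top[[nm]]))
  if (x$K > 5L) cat("  ...\n")
  invisible(x)
}

#' Compute the Rad-score
#'
#' The Rad-score of a patient is the linear combination of the signature's
#' selected features, each standardized with the training-cohort center and
#' scale, weighted by the averaged LASSO-Cox coefficients.
#'
#' @param model A `rad_signature`.
#' @param features Named numeric vector for one patient, or a matrix/data
#'   frame (columns named by feature) for many.
#' @return Numeric vector of Rad-scores.
#' @export
rad_score <- function(model, features) {
  stopifnot(inherits(model, "rad_signature"))
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(features)
  missing <- setdiff(model$selected, colnames(features))
  if (length(missing)) {
    stop("missing signature features: ", paste(missing, collapse = ", "))
  }
  z <- sweep(sweep(features[, model$selected, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  as.numeric(z %*% model$weights)
}

#' Serialize a radiomics signature to JSON
#'
#' @param model A `rad_signature`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "rad_signature"))
  jsonlite::write_json(
    list(
      manifest_version = "1.0", K = model$K, selected = model$selected,
      weights = as.list(model$weights), center = as.list(model$center),
      scale = as.list(model$scale), mean_n_selected = model$mean_n_selected,
      n_repeats = model$n_repeats, base_seed = model$base_seed
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a serialized radiomics signature
#'
#' @param path JSON path written by [write_signature()].
#' @return A `rad_signature`.
#' @export
read_signature <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(K = as.integer(j$K), selected = j$selected,
         weights = unlist(j$weights), center = unlist(j$center),
         scale = unlist(j$scale), mean_n_selected = j$mean_n_selected,
         n_repeats = as.integer(j$n_repeats),
         base_seed = as.integer(j$base_seed)),
    class = "rad_signature"
  )
}
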