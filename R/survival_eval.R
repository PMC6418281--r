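# Cox modelling and discrimination: proportional-hazards fits with Efron tie
# handling, Harrell's C-index, and the fixed-predictor bootstrap comparison
# of a clinicopathologic model against its radiomics-augmented counterpart.

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood fit (Efron tie handling, Newton iterations to a
#' relative log-likelihood change below 1e-9, at most 100 iterations) of all
#' columns of `design` as untransformed covariates. Delegates the
#' optimization to [survival::coxph()].
#'
#' @param design Data frame of covariates (numeric; 0/1 for binary factors).
#' @param time,event Survival time (months) and event indicator (0/1).
#' @return A `rad_coxfit`: list with the coefficient `table` (coef, se, HR,
#'   CI bounds, p), `coefficients`, `vcov`, `lp` (linear predictors),
#'   `n`, `n_events` and the underlying `fit`.
#' @export
fit_cox <- function(design, time, event) {
  design <- as.data.frame(design)
  if (anyNA(design) || anyNA(time) || anyNA(event)) {
    stop("missing values in survival data or covariates")
  }
  n_ev <- sum(event == 1)
  if (n_ev < 10 * ncol(design)) {
    warning("only ", n_ev, " events for ", ncol(design),
            " terms; estimates may be unstable")
  }
  dat <- cbind(data.frame(.time = time, .event = event), design)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")
  ))
  fit <- survival::coxph(
    fml, data = dat, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  )
  beta <- coef(fit)
  if (anyNA(beta) || any(abs(beta) > 50)) {
    stop("Cox fit did not converge to finite estimates ",
         "(possible monotone likelihood / perfect separation)")
  }
  se <- sqrt(diag(fit$var))
  tab <- data.frame(
    term = names(design),
    coef = unname(beta),
    se = unname(se),
    hr = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.96 * se)),
    ci_high = unname(exp(beta + 1.96 * se)),
    p = unname(2 * pnorm(-abs(beta / se))),
    binary = vapply(design, function(col) all(col %in% c(0, 1)), logical(1))
  )
  structure(
    list(table = tab, coefficients = beta, vcov = fit$var,
         lp = unname(fit$linear.predictors), n = nrow(design),
         n_events = n_ev, fit = fit),
    class = "rad_coxfit"
  )
}

#' @export
print.rad_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d subjects, %d events\n", x$n, x$n_events))
  tab <- x$table
  for (k in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s HR %6.3f (%.3f, %.3f)  p=%.4g\n", tab$term[k],
                tab$hr[k], tab$ci_low[k], tab$ci_high[k], tab$p[k]))
  }
  invisible(x)
}

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable when `time[i] < time[j]` and subject i had
#' the event; it is concordant when `risk[i] > risk[j]`, and tied risks
#' receive half credit: C = (concordant + 0.5 ties) / comparable.
#'
#' @param risk Per-subject risk scores (higher = higher hazard).
#' @param time,event Survival time and event indicator (0/1).
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  if (!all(is.finite(risk))) stop("risk scores must be finite")
  counts <- concordance_count_cpp(as.numeric(time), as.integer(event),
                                  as.numeric(risk))
  if (counts[3] == 0) stop("no comparable pairs: C-index undefined")
  (counts[1] + 0.5 * counts[2]) / counts[3]
}

#' Bootstrap comparison of two models' C-indices
#'
#' Holds each fitted model's linear predictor fixed, resamples subjects with
#' replacement `n_boot` times, recomputes both C-indices and their
#' difference per resample, and reports the percentile 95% CI of the
#' difference. Resamples without comparable pairs are redrawn. This is the
#' fixed-predictor (in-sample discrimination) comparison; set
#' `refit = TRUE` to refit both models on every resample instead.
#'
#' @param fit_base,fit_aug `rad_coxfit` objects fitted on the same subjects.
#' @param time,event Survival data of those subjects.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param refit Refit models per resample (slower; default `FALSE`).
#' @param design_base,design_aug Covariate tables, required when
#'   `refit = TRUE`.
#' @return A `cindex_comparison`: list with `c_base`, `c_aug`, `diff`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_redrawn`, `significant`.
#' @export
compare_models <- function(fit_base, fit_aug, time, event, n_boot = 1000L,
                           seed, refit = FALSE,
                           design_base = NULL, design_aug = NULL) {
  stopifnot(inherits(fit_base, "rad_coxfit"), inherits(fit_aug, "rad_coxfit"))
  n <- length(time)
  if (length(fit_base$lp) != n || length(fit_aug$lp) != n) {
    stop("both models must be fitted on the same subjects as `time`/`event`")
  }
  if (refit && (is.null(design_base) || is.null(design_aug))) {
    stop("refit = TRUE needs design_base and design_aug")
  }
  c_base <- concordance_index(fit_base$lp, time, event)
  c_aug <- concordance_index(fit_aug$lp, time, event)
  diffs <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- tryCatch({
        if (refit) {
          fb <- fit_cox(design_base[idx, , drop = FALSE], time[idx], event[idx])
          fa <- fit_cox(design_aug[idx, , drop = FALSE], time[idx], event[idx])
          cb <- concordance_index(fb$lp, time[idx], event[idx])
          ca <- concordance_index(fa$lp, time[idx], event[idx])
        } else {
          cb <- concordance_index(fit_base$lp[idx], time[idx], event[idx])
          ca <- concordance_index(fit_aug$lp[idx], time[idx], event[idx])
        }
        diffs[b] <- ca - cb
        TRUE
      }, error = function(e) FALSE)
      if (ok) b <- b + 1L else n_redrawn <- n_redrawn + 1L
    }
  })
  ci <- unname(quantile(diffs, c(0.025, 0.975)))
  structure(
    list(c_base = c_base, c_aug = c_aug, diff = c_aug - c_base,
         ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         n_redrawn = n_redrawn, seed = seed,
         significant = ci[1] > 0 || ci[2] < 0),
    class = "cindex_comparison"
  )
}

#' @export
print.cindex_comparison <- function(x, ...) {
  cat(sprintf(
    "C-index %.3f (base) vs %.3f (augmented); difference %.3f (95%% CI %.3f, %.3f)%s\n",
    x$c_base, x$c_aug, x$diff, x$ci_low, x$ci_high,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

format_hr <- function(hr, lo, hi, p, reference = FALSE) {
  if (reference) {
    data.frame(hr = "1", ci = "", p = "")
  } else {
    data.frame(
      hr = sprintf("%.3f", hr),
      ci = sprintf("%.3f, %.3f", lo, hi),
      p = ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
    )
  }
}

#' Assemble univariate and multivariate report tables
#'
#' Builds the standard reporting layout: one univariate Cox fit per
#' variable; the multivariate clinicopathologic model; the multivariate
#' radiomics model (clinicopathologic covariates plus Rad-score); and the
#' bootstrap C-index comparison. Reference levels of binary covariates are
#' rendered as HR 1 with an empty CI.
#'
#' @param univariate Named list of single-covariate `rad_coxfit` objects.
#' @param clin_fit,aug_fit Multivariate `rad_coxfit` objects.
#' @param comparison A `cindex_comparison`.
#' @return List of data frames `univariate`, `clinicopathologic`,
#'   `radiomics`, `cindex`.
#' @export
build_model_tables <- function(univariate, clin_fit, aug_fit, comparison) {
  render <- function(tb, labels) {
    do.call(rbind, lapply(seq_len(nrow(tb)), function(k) {
      row <- cbind(variable = labels[k],
                   format_hr(tb$hr[k], tb$ci_low[k], tb$ci_high[k], tb$p[k]))
      if (isTRUE(tb$binary[k])) {
        ref <- cbind(variable = paste0(labels[k], " (reference)"),
                     format_hr(NA, NA, NA, NA, reference = TRUE))
        row <- rbind(ref, row)
      }
      row
    }))
  }
  uni <- do.call(rbind, lapply(names(univariate), function(nm) {
    render(univariate[[nm]]$table, nm)
  }))
  multi <- function(fit) render(fit$table, fit$table$term)
  cidx <- data.frame(
    model = c("clinicopathologic", "radiomics", "difference"),
    c_index = c(sprintf("%.3f", comparison$c_base),
                sprintf("%.3f", comparison$c_aug),
                sprintf("%.3f", comparison$diff)),
    ci95 = c("", "", sprintf("%.3f, %.3f", comparison$ci_low,
                             comparison$ci_high))
  )
  list(univariate = uni, clinicopathologic = multi(clin_fit),
       radiomics = multi(aug_fit), cindex = cidx)
}
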