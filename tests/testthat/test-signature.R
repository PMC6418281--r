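# Small survival fixtures for the selection machinery.
sim_surv_features <- function(n, p, beta, seed, event_frac = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  lp <- as.numeric(x %*% beta)
  scale <- uniroot(function(s) {
    mean(1 - exp(-(120 / exp(s))^1.2 * exp(lp))) - event_frac
  }, c(-5, 25))$root
  t_ev <- exp(scale) * (-log(runif(n)) / exp(lp))^(1 / 1.2)
  t_c <- runif(n, 60, 160)
  list(x = x, time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

test_that("standardize z-scores with population SD and flags constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  x <- rbind(x, x, x, x, x, x, x, x, x, x)    # 30 rows
  fm <- standardize(x)
  expect_equal(sort(unique(round(fm$x[, "a"], 4))), c(-1.2247, 0, 1.2247))
  expect_true(fm$zero_var[["b"]])
  expect_true(all(fm$x[, "b"] == 0))
  expect_equal(unname(colMeans(fm$x)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(sqrt(colMeans(fm$x^2))), c(1, 0), tolerance = 1e-8)

  # idempotence: standardizing an already-standardized matrix changes nothing
  fm2 <- standardize(fm$x)
  expect_equal(fm2$x, fm$x, tolerance = 1e-12)

  xna <- x; xna[3, 1] <- NA
  expect_error(standardize(xna), "missing")
  expect_error(standardize(x[1:10, ]), "at least 30")
})

test_that("the penalty path shrinks everything at lambda_max and matches the
           unpenalized fit as the penalty vanishes", {
  d <- sim_surv_features(200, 3, beta = c(0.8, -0.5, 0), seed = 42)
  fm <- standardize(d$x)
  path <- lasso_cox_path(fm, d$time, d$event, lambda.min.ratio = 1e-6)
  expect_true(all(as.numeric(coef(path, s = max(path$lambda))) == 0))

  b_small <- as.numeric(coef(path, s = min(path$lambda)))
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ fm$x,
                         ties = "breslow")
  expect_equal(b_small, unname(coef(ref)), tolerance = 0.05)
})

test_that("cross-validated selection finds a strong single feature", {
  hits <- 0L
  for (s in 1:5) {
    d <- sim_surv_features(300, 20, beta = c(1, rep(0, 19)), seed = 100 + s)
    fm <- standardize(d$x)
    fit <- cv_lasso_cox_once(fm, d$time, d$event, fold_seed = s)
    if (fit$coefficients[1] != 0 &&
        which.max(abs(fit$coefficients)) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("cv_lasso_cox_once requires 10 events and is seed-reproducible", {
  d <- sim_surv_features(100, 5, beta = rep(0, 5), seed = 7, event_frac = 0.05)
  fm <- standardize(d$x)
  expect_error(cv_lasso_cox_once(fm, d$time, rep(0, 100), fold_seed = 1),
               "insufficient events")
  d2 <- sim_surv_features(150, 8, beta = c(1, rep(0, 7)), seed = 8)
  fm2 <- standardize(d2$x)
  r1 <- cv_lasso_cox_once(fm2, d2$time, d2$event, fold_seed = 5)
  r2 <- cv_lasso_cox_once(fm2, d2$time, d2$event, fold_seed = 5)
  expect_identical(r1, r2)
})

test_that("repeated selection averages coefficients and truncates to K", {
  d <- sim_surv_features(250, 15, beta = c(1, -0.8, rep(0, 13)), seed = 9)
  fm <- standardize(d$x)

  # single repetition: signature = the nonzero set of that repetition
  one <- cv_lasso_cox_once(fm, d$time, d$event, fold_seed = 30)
  sig1 <- repeated_cv_select(fm, d$time, d$event, n_repeats = 1,
                             base_seed = 30)
  expect_equal(sig1$K, one$n_selected)
  expect_setequal(sig1$selected, paste0("f", which(one$coefficients != 0)))

  # averaging: weights equal the elementwise mean of per-repetition fits
  reps <- lapply(0:2, function(r)
    cv_lasso_cox_once(fm, d$time, d$event, fold_seed = 40 + r)$coefficients)
  avg <- Reduce(`+`, reps) / 3
  sig3 <- repeated_cv_select(fm, d$time, d$event, n_repeats = 3,
                             base_seed = 40)
  expect_equal(unname(sig3$weights),
               avg[match(sig3$selected, paste0("f", 1:15))], tolerance = 1e-12)

  # bit-reproducibility
  sig3b <- repeated_cv_select(fm, d$time, d$event, n_repeats = 3,
                              base_seed = 40)
  expect_identical(sig3, sig3b)
})

test_that("the Rad-score is the weighted sum of standardized features", {
  model <- structure(
    list(K = 2L, selected = c("a", "b"),
         weights = c(a = 0.5, b = -0.2),
         center = c(a = 10, b = 0), scale = c(a = 2, b = 1)),
    class = "rad_signature"
  )
  expect_equal(rad_score(model, c(a = 14, b = 1)), 0.5 * 2 - 0.2 * 1)
  expect_equal(rad_score(model, c(a = 10, b = 0)), 0)   # mean profile
  expect_error(rad_score(model, c(a = 1)), "missing signature features: b")

  null_model <- model
  null_model$weights[] <- 0
  expect_equal(rad_score(null_model, c(a = 99, b = -3)), 0)

  # linearity: midpoint profile scores the mean of the endpoint scores
  p1 <- c(a = 8, b = 2); p2 <- c(a = 20, b = -4)
  expect_equal(rad_score(model, (p1 + p2) / 2),
               mean(rad_score(model, rbind(p1, p2))))
})

test_that("signatures survive a JSON round trip", {
  d <- sim_surv_features(200, 10, beta = c(1, rep(0, 9)), seed = 12)
  fm <- standardize(d$x)
  sig <- repeated_cv_select(fm, d$time, d$event, n_repeats = 2, base_seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$selected, sig$selected)
  expect_equal(back$weights, sig$weights, tolerance = 1e-12)
  scores_a <- rad_score(sig, d$x)
  scores_b <- rad_score(back, d$x)
  expect_equal(scores_a, scores_b, tolerance = 1e-12)
})
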