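test_that("pearson matrix is symmetric with unit diagonal and sane p-values", {
  cohort <- generate_cohort(eq1_cohort_spec(50, residual_sd = 0.5, seed = 1))
  cm <- pearson_matrix(cohort)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, length(feature_cols)))
  expect_true(all(abs(cm$r) <= 1))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
})

test_that("pearson matrix recovers a known correlation and the null", {
  set.seed(42)
  n <- 10000
  rho <- 0.827
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  dat <- tibble::tibble(a = x, b = y, c = rnorm(n))
  cm <- pearson_matrix(dat, c("a", "b", "c"))
  expect_equal(cm$r["a", "b"], 0.827, tolerance = 0.02 / 0.827)
  expect_lt(cm$p["a", "b"], 0.01)
  expect_lt(abs(cm$r["a", "c"]), 0.05)
})

test_that("zero-variance variables are flagged, not silently zeroed", {
  dat <- tibble::tibble(a = rnorm(20), b = rep(5, 20))
  expect_warning(cm <- pearson_matrix(dat, c("a", "b")), "zero-variance")
  expect_true(is.na(cm$r["a", "b"]))
  expect_equal(cm$zero_variance, "b")
})

test_that("OLS agrees with a brute-force normal-equations oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    dat <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p,
      dimnames = list(NULL, paste0("x", seq_len(p))))))
    dat$y <- rnorm(n)
    fit <- fit_ols(dat, "y", paste0("x", seq_len(p)))
    X <- cbind(1, as.matrix(dat[paste0("x", seq_len(p))]))
    beta <- solve(t(X) %*% X, t(X) %*% dat$y)  # independent oracle
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(drop(beta)), tolerance = 1e-8)
    expect_lt(abs(sum(fit$residuals)), 1e-8 * sd(dat$y) * n)
    # prediction at the predictor means equals the response mean
    at_means <- tibble::as_tibble(as.list(colMeans(dat)))
    expect_equal(predict(fit, newdata = at_means), mean(dat$y),
                 tolerance = 1e-8)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$adj_r_squared, fit$r_squared)
  }
})

test_that("a constant response yields zero slopes by convention", {
  dat <- tibble::tibble(x = rnorm(20), y = rep(3.5, 20))
  fit <- fit_ols(dat, "y", "x")
  expect_equal(unname(fit$coefficients[["x"]]), 0, tolerance = 1e-10)
  expect_equal(fit$intercept, 3.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 0)
})

test_that("rank-deficient designs error naming the collinear columns", {
  dat <- tibble::tibble(x1 = rnorm(20))
  dat$x2 <- dat$x1
  dat$y <- rnorm(20)
  expect_error(fit_ols(dat, "y", c("x1", "x2")), "x2",
               class = "kayakforce_error_estimation")
})

test_that("normal-theory CIs achieve near-nominal coverage", {
  hits <- vapply(1:100, function(s) {
    cohort <- generate_cohort(cohort_spec(
      n_paddlers = 50, coefficients = c(peak_force_N = 0.0045),
      intercept = 7.62, predictor_means = c(peak_force_N = 398),
      predictor_sds = c(peak_force_N = 106), residual_sd = 1, seed = s
    ))
    fit <- fit_ols(cohort, "velocity_kmh", "peak_force_N")
    ci <- fit$conf_int[fit$conf_int$term == "peak_force_N", ]
    ci$conf.low <= 0.0045 && 0.0045 <= ci$conf.high
  }, logical(1))
  expect_gte(sum(hits), 88)
})

test_that("BIC selection agrees with an independently coded enumeration", {
  cohort <- generate_cohort(eq1_cohort_spec(60, residual_sd = 0.3, seed = 2))
  cands <- c(eq1_predictors, "mean_force_N")
  best <- select_model_bic(cohort, "velocity_kmh", cands)

  # independent oracle: enumerate subsets, BIC from stats::lm + logLik form
  subsets <- unlist(lapply(seq_along(cands), function(k)
    utils::combn(cands, k, simplify = FALSE)), recursive = FALSE)
  oracle_bic <- vapply(subsets, function(pr) {
    m <- stats::lm(stats::reformulate(pr, "velocity_kmh"), data = cohort)
    n <- nobs(m)
    n * log(sum(resid(m)^2) / n) + (length(pr) + 1) * log(n)
  }, numeric(1))
  oracle_best <- subsets[[which.min(oracle_bic)]]
  expect_setequal(best$predictors, oracle_best)
  expect_equal(best$bic, min(oracle_bic), tolerance = 1e-10)
  # stats::BIC differs only by an additive constant, so it ranks identically
  oracle_bic2 <- vapply(subsets, function(pr)
    stats::BIC(stats::lm(stats::reformulate(pr, "velocity_kmh"),
                         data = cohort)), numeric(1))
  expect_equal(order(oracle_bic), order(oracle_bic2))
})

test_that("BIC selection handles single and degenerate candidate sets", {
  cohort <- generate_cohort(eq1_cohort_spec(30, residual_sd = 0.5, seed = 3))
  single <- select_model_bic(cohort, "velocity_kmh", "peak_force_N")
  expect_equal(single$predictors, "peak_force_N")

  dup <- dplyr::mutate(cohort, peak_copy_N = .data$peak_force_N)
  expect_warning(
    best <- select_model_bic(dup, "velocity_kmh",
                             c("peak_force_N", "peak_copy_N")),
    "skipping subset"
  )
  expect_length(best$predictors, 1)
})

test_that("BIC selection excludes a pure-noise candidate", {
  excluded <- vapply(1:20, function(s) {
    cohort <- generate_cohort(eq1_cohort_spec(200, residual_sd = 0.1,
                                              seed = s))
    set.seed(s + 5000)
    cohort$noise_var <- rnorm(200)
    best <- select_model_bic(cohort, "velocity_kmh",
                             c(eq1_predictors, "noise_var"))
    !("noise_var" %in% best$predictors)
  }, logical(1))
  # BIC admits a noise term with prob ~ P(chi2_1 > log n) ~ 2% at n = 200;
  # 17/20 bounds that well below the binomial noise floor (the tighter
  # 95/100 bound is asserted over 100 replicates in the acceptance suite)
  expect_gte(sum(excluded), 17)
})

test_that("the built-in velocity model evaluates its linear form", {
  rec <- tibble::tibble(peak_force_N = 0, impulse_10s_Ns = 0,
                        stroke_rate_spm = 0)
  expect_equal(predict_vmax(rec)$vmax_pred_kmh, 7.62)
  rec$stroke_rate_spm <- 100
  expect_equal(predict_vmax(rec)$vmax_pred_kmh, 12.62)
  expect_error(predict_vmax(tibble::tibble(peak_force_N = 1)),
               "impulse_10s_Ns", class = "kayakforce_error_validation")
})

test_that("cross-validation estimates the generating residual SD", {
  clean <- generate_cohort(eq1_cohort_spec(40, residual_sd = 0, seed = 4))
  cv0 <- cross_validate(clean, "velocity_kmh", eq1_predictors, seed = 1)
  expect_lt(cv0$error_sd, 1e-6)

  noisy <- generate_cohort(eq1_cohort_spec(200, residual_sd = 1, seed = 5))
  cv1 <- cross_validate(noisy, "velocity_kmh", eq1_predictors, seed = 2)
  expect_equal(cv1$error_sd, 1, tolerance = 0.15)

  cv2 <- cross_validate(noisy, "velocity_kmh", eq1_predictors, seed = 2)
  expect_identical(cv1$predictions, cv2$predictions)

  # folds partition the sample with sizes differing by at most one
  sizes <- table(cv1$predictions$fold)
  expect_equal(sum(sizes), 200)
  expect_lte(diff(range(sizes)), 1)

  expect_error(cross_validate(clean[1:8, ], "velocity_kmh",
                              eq1_predictors, k = 5),
               class = "kayakforce_error_parameter")

  loo <- cross_validate(clean, "velocity_kmh", eq1_predictors,
                        method = "loo")
  expect_equal(loo$k, 40)
})

test_that("explanatory fits recover slopes and honour adjustment", {
  spec <- cohort_spec(
    n_paddlers = 10000, direction = "feature_on_velocity",
    coefficients = c(mean_force_N = 14.13), intercept = 30,
    residual_sd = 5, seed = 6
  )
  fit <- explanatory_fit(generate_cohort(spec), "mean_force_N")
  expect_equal(fit$velocity_slope$estimate, 14.13, tolerance = 0.01)

  # a velocity-independent feature: the CI covers zero
  flat <- generate_cohort(cohort_spec(
    n_paddlers = 100, direction = "feature_on_velocity",
    coefficients = c(mean_force_N = 0), intercept = 200,
    residual_sd = 10, seed = 7
  ))
  fit0 <- explanatory_fit(flat, "mean_force_N")
  expect_lte(fit0$velocity_slope$conf.low, 0)
  expect_gte(fit0$velocity_slope$conf.high, 0)

  # group offsets but no slope difference: adjusted slope ~ univariate slope
  off <- generate_cohort(cohort_spec(
    n_paddlers = 2000, direction = "feature_on_velocity",
    coefficients = c(mean_force_N = 14.13), intercept = 30,
    residual_sd = 5, seed = 8,
    group_offsets = c(girls_u16 = -40, boys_u18 = 0, senior_women = -20,
                      senior_men = 30)
  ))
  uni <- explanatory_fit(off, "mean_force_N")
  adj <- explanatory_fit(off, "mean_force_N", adjusted = TRUE)
  expect_equal(adj$velocity_slope$estimate, uni$velocity_slope$estimate,
               tolerance = 0.05)
  expect_true("group" %in% adj$predictors)

  one_group <- dplyr::mutate(off, group = "senior_men")
  expect_warning(explanatory_fit(one_group, "mean_force_N", adjusted = TRUE),
                 "one group")
})

test_that("bootstrap CIs are seeded, tight when noiseless, and calibrated", {
  clean <- generate_cohort(eq1_cohort_spec(30, residual_sd = 0, seed = 9))
  ci <- bootstrap_ci(clean, "velocity_kmh", eq1_predictors, n_reps = 200,
                     seed = 1)
  expect_lt(max(ci$conf.high - ci$conf.low), 1e-6)

  noisy <- generate_cohort(eq1_cohort_spec(60, residual_sd = 1, seed = 10))
  a <- bootstrap_ci(noisy, "velocity_kmh", eq1_predictors, n_reps = 200,
                    seed = 3)
  b <- bootstrap_ci(noisy, "velocity_kmh", eq1_predictors, n_reps = 200,
                    seed = 3)
  expect_identical(a, b)
  expect_true(all(a$conf.low <= a$estimate & a$estimate <= a$conf.high))
})

test_that("diagnostics expose leverage, Cook's distance and residual sums", {
  cohort <- generate_cohort(eq1_cohort_spec(50, residual_sd = 0.5, seed = 11))
  fit <- fit_ols(cohort, "velocity_kmh", eq1_predictors)
  d <- model_diagnostics(fit)
  expect_equal(nrow(d), 50)
  expect_lt(abs(sum(d$.resid)), 1e-8)
  expect_true("paddler_id" %in% names(d))

  # a gross outlier gets the largest Cook's distance
  spoiled <- cohort
  spoiled$velocity_kmh[17] <- spoiled$velocity_kmh[17] + 25
  fit2 <- fit_ols(spoiled, "velocity_kmh", eq1_predictors)
  expect_equal(which.max(model_diagnostics(fit2)$.cooksd), 17)

  # perfectly balanced two-level duplicated design: all leverages equal
  set.seed(33)
  base <- tibble::tibble(x = rep(c(-1, 1), each = 10))
  base$y <- 2 * base$x + rnorm(20)
  fit3 <- fit_ols(base, "y", "x")
  h <- model_diagnostics(fit3)$.hat
  expect_equal(h, rep(h[1], 20), tolerance = 1e-12)
})

test_that("tidy and glance methods return the documented shapes", {
  cohort <- generate_cohort(eq1_cohort_spec(40, residual_sd = 0.5, seed = 12))
  fit <- fit_ols(cohort, "velocity_kmh", eq1_predictors)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$nobs, 40)
  expect_true(gl$adj.r.squared <= gl$r.squared)

  cv <- cross_validate(cohort, "velocity_kmh", eq1_predictors, seed = 1)
  expect_equal(nrow(tidy(cv)), 40)
  expect_equal(glance(cv)$k, 5)

  cm <- pearson_matrix(cohort)
  expect_equal(nrow(tidy(cm)), length(feature_cols)^2)
})
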