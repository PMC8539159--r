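#' Pearson correlation matrix of feature-table variables
#'
#' Pairwise Pearson correlations over complete cases, with two-sided
#' p-values from the t transform `t = r sqrt((n-2)/(1-r^2))`. Used as the
#' multicollinearity screen before fitting the velocity prediction model.
#' Zero-variance variables are flagged and their correlations reported as
#' `NA`, never silently set to zero.
#'
#' @param data A feature-record data frame.
#' @param variables Character vector of numeric columns; defaults to
#'   velocity plus the five force characteristics.
#' @return An object of class `kayak_cormat`: list with matrices `r` and
#'   `p`, the complete-case count `n`, and `zero_variance` names. Has
#'   [tidy()] and [autoplot()] methods.
#' @export
pearson_matrix <- function(data, variables = kf_feature_cols) {
  if (!is.data.frame(data)) kf_stop("`data` must be a data frame.",
                                    "validation")
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols)) {
    kf_stop(paste0("missing variable(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  x <- as.matrix(data[variables])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) kf_stop("need at least 3 complete records.", "insufficient_data")
  sds <- apply(x, 2, sd)
  zero_var <- variables[sds == 0]
  if (length(zero_var)) {
    warn(paste0("zero-variance variable(s), correlations undefined: ",
                paste(zero_var, collapse = ", ")))
  }
  r <- suppressWarnings(cor(x))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!(variables %in% zero_var)] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, variables = variables,
                 zero_variance = zero_var),
            class = "kayak_cormat")
}

#' Ordinary least squares fit of a feature-table model
#'
#' Fits `response ~ predictors` by OLS via [stats::lm()] and packages the
#' quantities the kayak analyses report: coefficients with normal-theory
#' 95% CIs, R-squared, adjusted R-squared, the overall F statistic, a
#' Gaussian-likelihood BIC (`n log(RSS/n) + p log(n)`, `p` counting intercept
#' and slopes), residuals and Cook's distances. Rank-deficient designs are
#' an error naming the collinear columns.
#'
#' @param data A data frame with the response and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names. Character
#'   (factor) predictors such as `group` are expanded to dummies by the
#'   usual treatment contrasts.
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return An object of class `kayak_fit` with [tidy()], [glance()],
#'   [predict()] and [autoplot()] methods.
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_paddlers = 50, coefficients = c(peak_force_N = 0.0045),
#'   intercept = 7.62, predictor_means = c(peak_force_N = 398),
#'   predictor_sds = c(peak_force_N = 106), residual_sd = 0.5, seed = 1
#' ))
#' fit <- fit_ols(cohort, "velocity_kmh", "peak_force_N")
#' glance(fit)
#' @export
fit_ols <- function(data, response, predictors, conf_level = 0.95) {
  if (!is.data.frame(data)) kf_stop("`data` must be a data frame.",
                                    "validation")
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    kf_stop(paste0("missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  data <- tibble::as_tibble(data)
  f <- reformulate(predictors, response)
  mm <- model.matrix(f, data)
  if (nrow(mm) <= ncol(mm)) {
    kf_stop("more model parameters than observations.", "estimation")
  }
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    kf_stop(paste0("rank-deficient design; collinear column(s): ",
                   paste(dropped, collapse = ", ")), "estimation")
  }
  fit <- lm(f, data = data)
  s <- suppressWarnings(summary(fit))  # "perfect fit" warning on clean data
  n <- nrow(mm)
  rss <- sum(residuals(fit)^2)
  p_par <- length(coef(fit))
  r2 <- s$r.squared
  adj_r2 <- s$adj.r.squared
  # a constant response has no variance to explain: R^2 is 0 by convention
  if (!is.finite(r2) || sd(data[[response]]) == 0) { r2 <- 0; adj_r2 <- 0 }
  fstat <- if (!is.null(s$fstatistic)) s$fstatistic else
    c(value = NA_real_, numdf = NA_real_, dendf = n - p_par)
  ci <- suppressWarnings(confint(fit, level = conf_level))
  structure(list(
    fit = fit,
    response = response, predictors = predictors,
    intercept = unname(coef(fit)[1]),
    coefficients = coef(fit)[-1],
    conf_int = tibble::tibble(
      term = rownames(ci), conf.low = ci[, 1], conf.high = ci[, 2]
    ),
    conf_level = conf_level,
    r_squared = r2, adj_r_squared = adj_r2,
    f_statistic = unname(fstat[1]), df = unname(fstat[2]),
    df_residual = unname(fstat[3]),
    bic = n * log(rss / n) + p_par * log(n),
    sigma = s$sigma, nobs = n,
    residuals = unname(residuals(fit)),
    cooks_distance = unname(cooks.distance(fit)),
    data = data
  ), class = "kayak_fit")
}

#' @export
print.kayak_fit <- function(x, ...) {
  cat("<kayak_fit> ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  print(coef(x$fit))
  cat(sprintf("R2 = %.3f (adj. %.3f), F(%g, %g) = %.2f, BIC = %.2f, n = %d\n",
              x$r_squared, x$adj_r_squared, x$df, x$df_residual,
              x$f_statistic, x$bic, x$nobs))
  invisible(x)
}

#' @export
predict.kayak_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(fitted(object$fit)))
  unname(predict(object$fit, newdata = tibble::as_tibble(newdata)))
}

#' Exhaustive BIC subset selection for the velocity model
#'
#' Fits every non-empty subset of the candidate predictors by OLS and
#' returns the fit minimising BIC (`n log(RSS/n) + p log(n)`). Ties are
#' broken toward fewer predictors, then lexicographically. Subsets that fail
#' to fit (e.g. collinear duplicates) are skipped with a warning.
#'
#' @param data A feature-record data frame.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictors (at most 15).
#' @return The winning `kayak_fit`, with attribute `search` — a tibble of
#'   every subset tried and its BIC.
#' @export
select_model_bic <- function(data, response, candidates) {
  if (length(candidates) < 1 || length(candidates) > 15) {
    kf_stop("between 1 and 15 candidate predictors are required.",
            "parameter")
  }
  subsets <- unlist(lapply(seq_along(candidates), function(k)
    combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  rows <- purrr::map(subsets, function(preds) {
    fit <- tryCatch(fit_ols(data, response, preds), error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("skipping subset {%s}: %s",
                   paste(preds, collapse = ", "), conditionMessage(fit)))
      return(NULL)
    }
    list(predictors = preds, n_predictors = length(preds), bic = fit$bic,
         fit = fit)
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) kf_stop("no candidate subset could be fitted.",
                             "estimation")
  search <- tibble::tibble(
    predictors = purrr::map_chr(rows, ~ paste(sort(.x$predictors),
                                              collapse = " + ")),
    n_predictors = purrr::map_int(rows, "n_predictors"),
    bic = purrr::map_dbl(rows, "bic")
  )
  ord <- order(search$bic, search$n_predictors, search$predictors)
  best <- rows[[ord[1]]]$fit
  attr(best, "search") <- search[order(search$bic), ]
  best
}

#' The published maximal-velocity prediction model
#'
#' The fixed-coefficient model relating a sprint kayaker's maximal paddling
#' velocity (km/h) to peak footrest force (N), force impulse over 10 s
#' (N·s) and stroke rate (strokes/min):
#' `Vmax = 0.0045 Fpeak + 0.0017 J10s + 0.05 SR + 7.62`.
#'
#' @return An object of class `vmax_model` usable in [predict_vmax()].
#' @export
vmax_published <- function() {
  structure(list(
    name = "published2021",
    intercept = 7.62,
    coefficients = c(peak_force_N = 0.0045, impulse_10s_Ns = 0.0017,
                     stroke_rate_spm = 0.05)
  ), class = "vmax_model")
}

#' Predict maximal paddling velocity from leg-force characteristics
#'
#' Evaluates a linear velocity model on each feature record. The default
#' model is the built-in published coefficient set ([vmax_published()]); a
#' `kayak_fit` (e.g. from [select_model_bic()]) can be supplied instead.
#'
#' @param records A feature-record data frame containing the model's
#'   predictor columns.
#' @param model A `vmax_model` or `kayak_fit`.
#' @return The input as a tibble with an added column `vmax_pred_kmh`.
#' @examples
#' rec <- tibble::tibble(peak_force_N = 398.2, impulse_10s_Ns = 2383.6,
#'                       stroke_rate_spm = 125)
#' predict_vmax(rec)$vmax_pred_kmh  # 19.71 km/h
#' @export
predict_vmax <- function(records, model = vmax_published()) {
  if (!is.data.frame(records)) {
    kf_stop("`records` must be a data frame.", "validation")
  }
  records <- tibble::as_tibble(records)
  if (inherits(model, "kayak_fit")) {
    records$vmax_pred_kmh <- predict(model, newdata = records)
    return(records)
  }
  if (!inherits(model, "vmax_model")) {
    kf_stop("`model` must be a vmax_model or kayak_fit.", "validation")
  }
  needed <- names(model$coefficients)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    kf_stop(paste0("missing predictor(s): ",
                   paste(missing_cols, collapse = ", ")), "validation")
  }
  lin <- as.matrix(records[needed]) %*% model$coefficients
  records$vmax_pred_kmh <- model$intercept + drop(lin)
  records
}

#' K-fold cross-validation of a velocity model
#'
#' Splits the records into `k` random folds of equal size (differing by at
#' most one), refits the OLS model on the other `k - 1` folds, predicts the
#' held-out fold, and reports the standard deviation of the held-out
#' prediction errors — the model's expected prediction spread in km/h. A
#' leave-one-out mode (`method = "loo"`) uses n folds of size one.
#'
#' @param data A feature-record data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictors.
#' @param k Number of folds (default 5); requires `n >= 2k`.
#' @param seed Integer seed for the fold assignment.
#' @param method `"kfold"` (default) or `"loo"`.
#' @return An object of class `kayak_cv`: list with `predictions` (tibble:
#'   `row`, `fold`, `observed`, `predicted`), `error_sd`, `k`, `seed`.
#' @export
cross_validate <- function(data, response, predictors, k = 5, seed = NULL,
                           method = c("kfold", "loo")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (method == "loo") {
    folds <- seq_len(n)
    k <- n
  } else {
    check_number(k, "k", lower = 2)
    if (n < 2 * k) {
      kf_stop(sprintf("need at least 2k = %d records for %d-fold CV, got %d.",
                      2 * k, k, n), "parameter")
    }
    if (!is.null(seed)) set.seed(seed)
    folds <- sample(rep_len(seq_len(k), n))
  }
  preds <- purrr::map_dfr(seq_len(k), function(fold) {
    hold <- which(folds == fold)
    fit <- fit_ols(data[-hold, ], response, predictors)
    tibble::tibble(
      row = hold, fold = fold,
      observed = data[[response]][hold],
      predicted = predict(fit, newdata = data[hold, ])
    )
  })
  preds <- dplyr::arrange(preds, .data$row)
  structure(list(
    predictions = preds,
    error_sd = sd(preds$observed - preds$predicted),
    k = k, seed = seed, method = method,
    response = response, predictors = predictors
  ), class = "kayak_cv")
}

#' Explanatory fit of a force characteristic on velocity
#'
#' The explanatory analyses invert the prediction question: how much does a
#' leg-force characteristic increase per km/h of paddling velocity?
#' `adjusted = TRUE` adds the paddler group (age/sex level) as a categorical
#' covariate, the "mutually adjusted" reading; `joint = TRUE` additionally
#' adjusts for the remaining force characteristics.
#'
#' @param data A feature-record data frame (normally several bouts per
#'   paddler).
#' @param feature Which force characteristic is the response, e.g.
#'   `"mean_force_N"`.
#' @param adjusted Adjust for `group` as a categorical covariate.
#' @param joint Also adjust for the other force characteristics.
#' @return A `kayak_fit`; its `velocity_slope` element holds the slope of
#'   velocity with its confidence interval.
#' @export
explanatory_fit <- function(data, feature, adjusted = FALSE, joint = FALSE) {
  data <- tibble::as_tibble(data)
  if (!feature %in% setdiff(kf_feature_cols, "velocity_kmh")) {
    kf_stop(sprintf("`feature` must be one of: %s.",
                    paste(setdiff(kf_feature_cols, "velocity_kmh"),
                          collapse = ", ")), "validation")
  }
  predictors <- "velocity_kmh"
  if (adjusted) {
    n_groups <- length(unique(stats::na.omit(data$group)))
    if (n_groups < 2) {
      warn("only one group present; adjusted fit degenerates to univariate.")
    } else {
      predictors <- c(predictors, "group")
    }
  }
  if (joint) {
    predictors <- c(predictors,
                    setdiff(kf_feature_cols, c("velocity_kmh", feature)))
  }
  fit <- fit_ols(data, feature, predictors)
  ci <- fit$conf_int[fit$conf_int$term == "velocity_kmh", ]
  fit$velocity_slope <- tibble::tibble(
    term = "velocity_kmh",
    estimate = unname(coef(fit$fit)["velocity_kmh"]),
    conf.low = ci$conf.low, conf.high = ci$conf.high
  )
  fit
}

#' Case-resampling bootstrap confidence intervals for OLS coefficients
#'
#' Resamples records with replacement, refits the OLS model on each
#' resample, and reports percentile confidence intervals per coefficient.
#' Case resampling makes no normality assumption about the residuals, which
#' is why it is used as the sensitivity check on the normal-theory CIs. A
#' resample with a rank-deficient design is redrawn (at most 10 retries).
#'
#' @param data A feature-record data frame with at least 10 rows.
#' @param response Response column name.
#' @param predictors Character vector of predictors.
#' @param n_reps Number of bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `term`, `estimate` (full-sample),
#'   `conf.low`, `conf.high`; attribute `replicates` holds the coefficient
#'   draws.
#' @export
bootstrap_ci <- function(data, response, predictors, n_reps = 1000,
                         seed = NULL, conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 10) kf_stop("need at least 10 records to bootstrap.", "parameter")
  check_number(n_reps, "n_reps", lower = 1)
  full <- fit_ols(data, response, predictors, conf_level = conf_level)
  mm <- model.matrix(reformulate(predictors, response), data)
  y <- data[[response]]
  p <- ncol(mm)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, n_reps, p, dimnames = list(NULL, colnames(mm)))
  for (b in seq_len(n_reps)) {
    for (try in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- mm[idx, , drop = FALSE]
      if (qr(xb)$rank == p) break
      if (try == 10) kf_stop("could not draw a full-rank bootstrap resample.",
                             "estimation")
    }
    draws[b, ] <- qr.coef(qr(xb), y[idx])
  }
  alpha <- (1 - conf_level) / 2
  qs <- apply(draws, 2, quantile, probs = c(alpha, 1 - alpha))
  out <- tibble::tibble(
    term = colnames(mm),
    estimate = unname(coef(full$fit)[colnames(mm)]),
    conf.low = qs[1, ], conf.high = qs[2, ]
  )
  attr(out, "replicates") <- draws
  attr(out, "n_reps") <- n_reps
  out
}

#' Residual diagnostics of a fitted model
#'
#' The numeric material behind the three standard regression diagnostic
#' plots: residuals vs fitted values, a normal Q-Q comparison of the
#' standardized residuals, and Cook's distances with leverages. If the
#' fitted data carry a `paddler_id` column it is included, so residuals can
#' be grouped by paddler to eyeball the correlated-design concern of
#' repeated bouts.
#'
#' @param fit A `kayak_fit`.
#' @return A tibble with one row per observation: `.fitted`, `.resid`,
#'   `.std.resid`, `.qq.theoretical` (normal quantile matched by rank),
#'   `.hat`, `.cooksd`, and `paddler_id` when available.
#' @export
model_diagnostics <- function(fit) {
  if (!inherits(fit, "kayak_fit")) {
    kf_stop("`fit` must be a kayak_fit.", "validation")
  }
  lmfit <- fit$fit
  std <- rstandard(lmfit)
  out <- tibble::tibble(
    .fitted = unname(fitted(lmfit)),
    .resid = unname(residuals(lmfit)),
    .std.resid = unname(std),
    .qq.theoretical = qnorm(ppoints(length(std)))[rank(std,
                                                       ties.method = "first")],
    .hat = unname(hatvalues(lmfit)),
    .cooksd = unname(cooks.distance(lmfit))
  )
  if ("paddler_id" %in% names(fit$data)) {
    out$paddler_id <- fit$data$paddler_id
  }
  out
}
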