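#' Tidy a kayak model fit
#'
#' @param x A `kayak_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.kayak_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
  dplyr::left_join(out, x$conf_int, by = "term")
}

#' @rdname tidy.kayak_fit
#' @return For `glance()`: a one-row tibble of fit statistics
#'   (`r.squared`, `adj.r.squared`, `sigma`, `statistic`, `df`,
#'   `df.residual`, `bic`, `nobs`).
#' @export
glance.kayak_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    sigma = x$sigma, statistic = x$f_statistic,
    df = x$df, df.residual = x$df_residual,
    bic = x$bic, nobs = x$nobs
  )
}

#' Tidy a correlation matrix
#'
#' @param x A `kayak_cormat`.
#' @param ... Unused.
#' @return A long tibble with one row per ordered variable pair: `var1`,
#'   `var2`, `r`, `p.value`.
#' @export
tidy.kayak_cormat <- function(x, ...) {
  grid <- expand.grid(var1 = x$variables, var2 = x$variables,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    var1 = grid$var1, var2 = grid$var2,
    r = as.vector(x$r), p.value = as.vector(x$p)
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `kayak_cv`.
#' @param ... Unused.
#' @return For `tidy()`: the per-record held-out predictions. For
#'   `glance()`: a one-row tibble with `error_sd`, `k`, `nobs`.
#' @export
tidy.kayak_cv <- function(x, ...) x$predictions

#' @rdname tidy.kayak_cv
#' @export
glance.kayak_cv <- function(x, ...) {
  tibble::tibble(error_sd = x$error_sd, k = x$k,
                 nobs = nrow(x$predictions), method = x$method)
}

#' @export
print.kayak_cv <- function(x, ...) {
  cat(sprintf("<kayak_cv> %d-fold (%s): held-out prediction-error SD = %.3f\n",
              x$k, x$method, x$error_sd))
  invisible(x)
}

#' @export
print.kayak_cormat <- function(x, ...) {
  cat(sprintf("<kayak_cormat> %d variables, n = %d complete records\n",
              length(x$variables), x$n))
  print(round(x$r, 3))
  invisible(x)
}
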