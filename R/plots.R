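#' Plot a normalized stroke-cycle force profile
#'
#' Ensemble mean force of the left and right footrest over the percent
#' stroke cycle, with a mean ± SD ribbon per side. The left peak anchors 0%
#' (and 100%); the right push lands near 50%.
#'
#' @param object A `normalized_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.normalized_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"percent",
    names_to = c("side", ".value"), names_pattern = "(left|right)_(.*)"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$percent, .data$mean_N,
                                     colour = .data$side,
                                     fill = .data$side)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_N - .data$sd_N,
                                      ymax = .data$mean_N + .data$sd_N),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Stroke cycle (%)", y = "Footrest force (N)",
                  colour = "Side", fill = "Side") +
    ggplot2::theme_minimal()
}

#' Plot a force trace
#'
#' @param object A [force_trace()].
#' @param window Optional `c(start, end)` in seconds to restrict the view.
#' @param ... Unused.
#' @return A ggplot of both channels against time.
#' @export
autoplot.force_trace <- function(object, window = NULL, ...) {
  dat <- tibble::as_tibble(object)
  if (!is.null(window)) {
    dat <- dplyr::filter(dat, .data$time_s >= window[1],
                         .data$time_s <= window[2])
  }
  long <- tidyr::pivot_longer(dat, -"time_s", names_to = "side",
                              values_to = "force_N")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$force_N,
                                     colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "Force (N)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix
#'
#' @param object A `kayak_cormat` from [pearson_matrix()].
#' @param ... Unused.
#' @return A ggplot heat map of the pairwise Pearson correlations.
#' @export
autoplot.kayak_cormat <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$var1, .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Diagnostic plots for a kayak model fit
#'
#' @param object A `kayak_fit`.
#' @param type `"residuals"` (residuals vs fitted), `"qq"` (normal Q-Q of
#'   standardized residuals), or `"cooks"` (Cook's distance per
#'   observation).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kayak_fit <- function(object, type = c("residuals", "qq", "cooks"),
                               ...) {
  type <- match.arg(type)
  d <- model_diagnostics(object)
  switch(type,
    residuals = ggplot2::ggplot(d, ggplot2::aes(.data$.fitted,
                                                .data$.resid)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Fitted values", y = "Residuals") +
      ggplot2::theme_minimal(),
    qq = ggplot2::ggplot(d, ggplot2::aes(.data$.qq.theoretical,
                                         .data$.std.resid)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Theoretical quantiles",
                    y = "Standardized residuals") +
      ggplot2::theme_minimal(),
    cooks = ggplot2::ggplot(
      dplyr::mutate(d, obs = dplyr::row_number()),
      ggplot2::aes(.data$obs, .data$.cooksd)) +
      ggplot2::geom_col(width = 0.2) +
      ggplot2::labs(x = "Observation", y = "Cook's distance") +
      ggplot2::theme_minimal()
  )
}

#' Plot held-out cross-validation predictions
#'
#' @param object A `kayak_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot of predicted vs observed velocity, one point per
#'   held-out record.
#' @export
autoplot.kayak_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$predicted,
                               colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed velocity (km/h)",
                  y = "Held-out prediction (km/h)", colour = "Fold") +
    ggplot2::theme_minimal()
}
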