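#' Construct a two-channel footrest force trace
#'
#' A force trace holds uniformly sampled left and right footrest force
#' channels (newtons) on a shared time base (seconds). This is the container
#' every preprocessing and feature function consumes.
#'
#' @param data A data frame with numeric columns `time_s`, `left_N`,
#'   `right_N`.
#' @param sampling_rate Sampling rate in Hz. If `NULL`, inferred from the
#'   median time step.
#' @return A tibble of class `force_trace` with attribute `sampling_rate`.
#' @examples
#' tr <- force_trace(data.frame(
#'   time_s = (0:9) / 10, left_N = rep(100, 10), right_N = rep(80, 10)
#' ))
#' sampling_rate(tr)
#' @export
force_trace <- function(data, sampling_rate = NULL) {
  data <- as_trace_tibble(data, c("time_s", "left_N", "right_N"))
  validate_time_base(data$time_s)
  dt <- stats::median(diff(data$time_s))
  fs <- sampling_rate %||% (1 / dt)
  if (abs(dt - 1 / fs) > 1e-9) {
    kf_stop(sprintf(
      "sampling_rate %g Hz is inconsistent with the observed time step %g s.",
      fs, dt
    ), "validation")
  }
  if (max(abs(diff(data$time_s) - dt)) > 1e-9) {
    kf_stop("time base is not uniform (time steps differ by more than 1e-9 s).",
            "data")
  }
  structure(data, sampling_rate = fs,
            class = c("force_trace", class(tibble::tibble())))
}

#' Construct a velocity trace
#'
#' @param data A data frame with numeric columns `time_s` and
#'   `velocity_kmh` (km/h, non-negative).
#' @return A tibble of class `velocity_trace`.
#' @export
velocity_trace <- function(data) {
  data <- as_trace_tibble(data, c("time_s", "velocity_kmh"))
  validate_time_base(data$time_s, uniform = FALSE)
  if (any(data$velocity_kmh < 0)) {
    kf_stop("velocities must be non-negative.", "validation")
  }
  structure(data, class = c("velocity_trace", class(tibble::tibble())))
}

#' Sampling rate of a force trace
#' @param trace A [force_trace()].
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(trace) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) kf_stop("object has no sampling_rate attribute.", "validation")
  fs
}

as_trace_tibble <- function(data, cols) {
  if (!is.data.frame(data)) {
    kf_stop("`data` must be a data frame.", "validation")
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    kf_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  data <- tibble::as_tibble(data)[cols]
  not_num <- cols[!vapply(data, is.numeric, logical(1))]
  if (length(not_num)) {
    kf_stop(paste0("column(s) not numeric: ", paste(not_num, collapse = ", ")),
            "format")
  }
  if (anyNA(data)) kf_stop("missing values are not allowed in traces.", "data")
  data
}

validate_time_base <- function(time_s, uniform = TRUE) {
  if (length(time_s) >= 2) {
    d <- diff(time_s)
    bad <- which(d <= 0)
    if (length(bad)) {
      kf_stop(sprintf(
        "time must be strictly increasing; first offending row: %d.",
        bad[1] + 1L
      ), "data")
    }
  }
  invisible(time_s)
}
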