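#' Choose the 10-s analysis window of a bout
#'
#' The impulse-over-10-s characteristic (and, by default, stroke rate, mean
#' force and velocity) is computed over a fixed 10-s window. The default
#' takes the last 10 s of the recording, the steadiest part of a bout with a
#' rolling start; the first 10 s or an explicit window can be requested
#' instead.
#'
#' @param trace A [force_trace()].
#' @param rule `"last-10s"` (default), `"first-10s"`, or `"explicit"`.
#' @param width_s Window width in seconds (default 10).
#' @param explicit Length-2 numeric `c(start, end)` in seconds, required when
#'   `rule = "explicit"`.
#' @return Numeric `c(start, end)` with attribute `rule`.
#' @export
analysis_window <- function(trace, rule = c("last-10s", "first-10s", "explicit"),
                            width_s = 10, explicit = NULL) {
  rule <- match.arg(rule)
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  t0 <- trace$time_s[1]
  t1 <- trace$time_s[nrow(trace)]
  win <- switch(rule,
    "last-10s" = c(t1 - width_s, t1),
    "first-10s" = c(t0, t0 + width_s),
    "explicit" = {
      if (is.null(explicit) || length(explicit) != 2) {
        kf_stop("`explicit` must be c(start, end).", "parameter")
      }
      as.numeric(explicit)
    }
  )
  dt <- 1 / sampling_rate(trace)
  if (win[1] < t0 - dt || win[2] > t1 + dt || win[2] <= win[1]) {
    kf_stop("analysis window falls outside the trace.", "parameter")
  }
  structure(win, rule = rule)
}

#' Stroke rate from detected peaks
#'
#' Strokes per minute over a time window, counting every push peak on both
#' sides (one left push + one right push = two strokes).
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param window Numeric `c(start, end)` in seconds, e.g. from
#'   [analysis_window()].
#' @return Stroke rate in strokes/min.
#' @export
stroke_rate <- function(peaks, window) {
  if (!inherits(peaks, "peak_set")) {
    kf_stop("`peaks` must be a peak_set.", "validation")
  }
  dur <- window[2] - window[1]
  if (!is.finite(dur) || dur <= 0) {
    kf_stop("window must have positive duration.", "parameter")
  }
  inside <- function(t) sum(t >= window[1] & t <= window[2])
  n <- inside(peaks$left$time_s) + inside(peaks$right$time_s)
  n * 60 / dur
}

#' Mean push force over a window
#'
#' Time-average of the two channels' mean, `(left + right) / 2`, over the
#' analysis window, troughs included.
#'
#' @param trace A (filtered) [force_trace()].
#' @param window Numeric `c(start, end)` in seconds.
#' @return Mean force in newtons.
#' @export
mean_force <- function(trace, window) {
  sel <- window_samples(trace, window)
  mean((trace$left_N[sel] + trace$right_N[sel]) / 2)
}

#' Mean per-cycle peak force
#'
#' Each analysed stroke cycle contributes its left-channel maximum and its
#' right-channel maximum; the reported peak force is the mean of all those
#' per-cycle per-side maxima, both sides pooled.
#'
#' @param cycles A `stroke_cycles` tibble from [segment_cycles()].
#' @return Peak force in newtons.
#' @export
peak_force <- function(cycles) {
  if (!inherits(cycles, "stroke_cycles") || nrow(cycles) == 0) {
    kf_stop("`cycles` must be a non-empty stroke_cycles tibble.",
            "insufficient_data")
  }
  maxima <- c(vapply(cycles$left, max, numeric(1)),
              vapply(cycles$right, max, numeric(1)))
  mean(maxima)
}

#' Total force impulse over an interval
#'
#' Trapezoid-rule integral of each channel over the interval, left and right
#' summed: the total push impulse in newton-seconds.
#'
#' @param trace A [force_trace()].
#' @param interval Numeric `c(start, end)` in seconds, inside the trace.
#' @return Impulse in N·s.
#' @export
impulse <- function(trace, interval) {
  sel <- window_samples(trace, interval)
  t <- trace$time_s[sel]
  pracma::trapz(t, trace$left_N[sel]) + pracma::trapz(t, trace$right_N[sel])
}

#' Mean impulse per stroke cycle
#'
#' Trapezoid-rule impulse (both sides summed) of each analysed cycle,
#' averaged over the cycles — one number per bout.
#'
#' @param cycles A `stroke_cycles` tibble.
#' @return Mean per-cycle impulse in N·s.
#' @export
impulse_per_cycle <- function(cycles) {
  if (!inherits(cycles, "stroke_cycles") || nrow(cycles) == 0) {
    kf_stop("`cycles` must be a non-empty stroke_cycles tibble.",
            "insufficient_data")
  }
  dt <- 1 / attr(cycles, "sampling_rate")
  per_cycle <- purrr::map2_dbl(cycles$left, cycles$right, function(l, r) {
    x <- (seq_along(l) - 1) * dt
    pracma::trapz(x, l) + pracma::trapz(x, r)
  })
  mean(per_cycle)
}

window_samples <- function(trace, window) {
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  if (length(window) != 2 || window[2] <= window[1]) {
    kf_stop("window must be c(start, end) with end > start.", "parameter")
  }
  dt <- 1 / sampling_rate(trace)
  if (window[1] < trace$time_s[1] - dt ||
      window[2] > trace$time_s[nrow(trace)] + dt) {
    kf_stop("interval falls outside the trace.", "parameter")
  }
  sel <- which(trace$time_s >= window[1] - dt / 2 &
               trace$time_s <= window[2] + dt / 2)
  if (length(sel) < 2) kf_stop("interval contains fewer than two samples.",
                               "insufficient_data")
  sel
}

#' Extract the five leg-force characteristics of a bout
#'
#' Runs the full descriptive pipeline on a raw force trace: zero-phase
#' low-pass filtering, per-side peak detection, left-anchored stroke-cycle
#' segmentation, selection of the analysed cycles, and computation of
#' stroke rate, mean force, peak force, impulse per stroke cycle and impulse
#' over 10 s. Velocity is the mean of the velocity trace over the analysis
#' window.
#'
#' @param trace A raw [force_trace()].
#' @param velocity A [velocity_trace()] for the same bout, or `NULL`
#'   (velocity reported as `NA`).
#' @param config Pipeline parameters, see [default_config()].
#' @param paddler_id,group,bout Identifying metadata copied into the record.
#' @return A one-row tibble feature record with attribute `profile` (the
#'   [normalize_and_average()] result for the analysed cycles).
#' @examples
#' sess <- generate_force_session(session_spec(duration = 20, noise_sd = 0))
#' vel <- generate_velocity_trace(20, 19.7)
#' extract_features(sess$trace, vel)
#' @export
extract_features <- function(trace, velocity = NULL, config = default_config(),
                             paddler_id = "P001", group = NA_character_,
                             bout = NA_character_) {
  filtered <- lowpass_filter(trace, cutoff = config$filter$cutoff_hz,
                             order = config$filter$order)
  peaks <- detect_peaks(filtered,
                        min_separation = config$peaks$min_separation_s,
                        min_prominence = config$peaks$min_prominence_N)
  if (nrow(peaks$left) < 2) {
    kf_stop("no stroke cycles detected in the trace.", "insufficient_data")
  }
  cycles <- segment_cycles(peaks, filtered)
  n_avail <- nrow(cycles)
  n_used <- min(config$cycles$n_cycles, n_avail)
  used <- cycles_slice(cycles, if (config$cycles$selection == "last")
    seq.int(n_avail - n_used + 1, n_avail) else seq_len(n_used))
  win <- analysis_window(filtered, rule = config$window$rule,
                         width_s = config$window$width_s,
                         explicit = config$window$explicit)
  profile <- normalize_and_average(used, n_cycles = n_used,
                                   grid_points = config$cycles$grid_points)

  vel_kmh <- NA_real_
  if (!is.null(velocity)) {
    if (!inherits(velocity, "velocity_trace")) {
      kf_stop("`velocity` must be a velocity_trace.", "validation")
    }
    vsel <- velocity$time_s >= win[1] & velocity$time_s <= win[2]
    vel_kmh <- if (any(vsel)) mean(velocity$velocity_kmh[vsel]) else
      mean(velocity$velocity_kmh)
  }

  rec <- tibble::tibble(
    paddler_id = paddler_id, group = group, bout = bout,
    velocity_kmh = vel_kmh,
    stroke_rate_spm = stroke_rate(peaks, win),
    mean_force_N = mean_force(filtered, win),
    peak_force_N = peak_force(used),
    impulse_cycle_Ns = impulse_per_cycle(used),
    impulse_10s_Ns = impulse(filtered, win)
  )
  attr(rec, "profile") <- profile
  rec
}

#' Default pipeline configuration
#'
#' All tunable parameters of the trace-to-features pipeline in one list:
#' filter cutoff/order, peak-detection thresholds, which and how many cycles
#' to average, and the 10-s analysis-window rule. Write to or read from YAML
#' with [write_config()] / [read_config()].
#'
#' @return A nested list of class `kayak_config`.
#' @export
default_config <- function() {
  structure(list(
    filter = list(cutoff_hz = 20, order = 4),
    peaks = list(min_separation_s = 0.15, min_prominence_N = NULL),
    cycles = list(n_cycles = 15, selection = "last", grid_points = 101),
    window = list(rule = "last-10s", width_s = 10, explicit = NULL)
  ), class = "kayak_config")
}
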