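#' Zero-phase Butterworth low-pass filter
#'
#' Filters each force channel independently with a Butterworth low-pass
#' filter applied forward and backward (zero-phase), the de-facto standard
#' for biomechanical force signals. Zero-phase filtering preserves the
#' timing of force peaks, on which stroke-cycle segmentation relies; the
#' effective attenuation is the squared magnitude response of the design.
#' Both signal ends are odd-reflection padded before filtering so that edge
#' transients decay inside the padding rather than in the data.
#'
#' @param trace A [force_trace()].
#' @param cutoff Cutoff frequency in Hz (default 20). Must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @return A filtered [force_trace()] on the same time base.
#' @export
lowpass_filter <- function(trace, cutoff = 20, order = 4) {
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  fs <- sampling_rate(trace)
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  check_number(order, "order", lower = 1)
  if (cutoff >= fs / 2) {
    kf_stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz.",
                    cutoff, fs / 2), "parameter")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- trace
  out$left_N <- filtfilt_padded(bf, trace$left_N, fs, cutoff)
  out$right_N <- filtfilt_padded(bf, trace$right_N, fs, cutoff)
  out
}

# forward-backward filtering with odd-reflection padding; the pad length
# (6 cycles of the cutoff period) lets startup transients decay to float
# noise before the retained samples
filtfilt_padded <- function(bf, x, fs, cutoff) {
  n <- length(x)
  p <- min(n - 1, ceiling(6 * fs / cutoff))
  if (p < 1) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[(p + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(p + 1):(p + n)]
}

#' Detect per-side push peaks
#'
#' Finds local maxima in each force channel, keeps those whose topographic
#' prominence reaches `min_prominence`, and enforces a minimum temporal
#' separation by greedily keeping the tallest peaks first. Apply after
#' [lowpass_filter()]; on raw noisy data every noise ripple is a local
#' maximum.
#'
#' @param trace A [force_trace()] (normally already filtered).
#' @param min_separation Minimum time between retained peaks on one side, in
#'   seconds. The default 0.15 s corresponds to a ceiling stroke rate of
#'   200 strokes/min (per-push period 0.3 s).
#' @param min_prominence Minimum peak prominence in newtons. `NULL` (default)
#'   uses 25% of the channel's 95th force percentile, which rejects noise
#'   ripples without assuming a stroke rate.
#' @return A list of class `peak_set` with tibbles `left` and `right`
#'   (columns `index`, `time_s`, `force_N`).
#' @export
detect_peaks <- function(trace, min_separation = 0.15, min_prominence = NULL) {
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  check_number(min_separation, "min_separation", lower = 0,
               strict_lower = TRUE)
  check_number(min_prominence, "min_prominence", lower = 0, allow_null = TRUE)
  fs <- sampling_rate(trace)
  one_side <- function(x) {
    thr <- min_prominence %||% (0.25 * quantile(x, 0.95, names = FALSE))
    idx <- find_prominent_peaks(x, thr, round(min_separation * fs))
    tibble::tibble(index = idx, time_s = trace$time_s[idx], force_N = x[idx])
  }
  structure(list(left = one_side(trace$left_N),
                 right = one_side(trace$right_N),
                 min_separation = min_separation),
            class = "peak_set")
}

# local maxima (plateau-aware: the centre sample of a flat top), prominence
# by the standard walk-to-higher-ground rule, then greedy tallest-first
# separation enforcement
find_prominent_peaks <- function(x, min_prominence, min_gap) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  is_peak <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                 r$values[2:(k - 1)] > r$values[3:k], FALSE)
  cand <- as.integer((starts[is_peak] + ends[is_peak]) / 2)
  if (!length(cand)) return(integer(0))

  prominence <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i
    while (j > 1 && x[j - 1] <= h) {
      j <- j - 1
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- h
    j <- i
    while (j < n && x[j + 1] <= h) {
      j <- j + 1
      if (x[j] < rmin) rmin <- x[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prominence >= min_prominence]
  if (length(cand) < 2) return(cand)

  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Segment left-anchored stroke cycles
#'
#' Cuts the trace into stroke cycles running from one left-side force peak
#' to the next, the anchoring convention for on-water kayak force profiles:
#' 0% of the cycle is a left-footrest peak, and the right-side push falls
#' near 50%. With `k` left peaks this yields `k - 1` cycles that tile the
#' span between the first and last left peak.
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param trace The [force_trace()] the peaks were detected on.
#' @return A tibble of class `stroke_cycles`, one row per cycle, with the
#'   per-side force segments as list columns (`left`, `right`), boundary
#'   indices/times and the cycle duration.
#' @export
segment_cycles <- function(peaks, trace) {
  if (!inherits(peaks, "peak_set")) {
    kf_stop("`peaks` must be a peak_set.", "validation")
  }
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  li <- peaks$left$index
  if (length(li) < 2) {
    kf_stop("at least two left-side peaks are needed to delimit a stroke cycle.",
            "insufficient_data")
  }
  fs <- sampling_rate(trace)
  cycles <- purrr::map_dfr(seq_len(length(li) - 1), function(k) {
    s <- li[k]; e <- li[k + 1]
    tibble::tibble(
      cycle = k, start_index = s, end_index = e,
      start_time_s = trace$time_s[s], end_time_s = trace$time_s[e],
      duration_s = trace$time_s[e] - trace$time_s[s],
      left = list(trace$left_N[s:e]),
      right = list(trace$right_N[s:e])
    )
  })
  structure(cycles, sampling_rate = fs,
            class = c("stroke_cycles", class(tibble::tibble())))
}

# row subsetting that keeps the stroke_cycles class and sampling_rate
# (tibble subsetting drops both)
cycles_slice <- function(cycles, idx) {
  out <- tibble::as_tibble(cycles)[idx, ]
  structure(out, sampling_rate = attr(cycles, "sampling_rate"),
            class = c("stroke_cycles", class(tibble::tibble())))
}

#' Time-normalize stroke cycles and ensemble-average them
#'
#' Resamples each stroke cycle onto a common percent-of-cycle grid by linear
#' interpolation (0% and 100% are consecutive left-side peaks) and returns
#' the pointwise ensemble mean and standard deviation of each channel — the
#' classic cycle-normalized force profile. By default the last
#' `n_cycles` complete cycles are averaged, the steadiest regime of a bout;
#' if fewer are available all cycles are used and the result is flagged.
#'
#' @param cycles A `stroke_cycles` tibble from [segment_cycles()].
#' @param n_cycles Number of cycles to average (default 15).
#' @param grid_points Number of percent-grid points (default 101: 0, 1, ...,
#'   100).
#' @param selection `"last"` (default) or `"first"`: which end of the bout
#'   the averaged cycles are taken from.
#' @return A tibble of class `normalized_profile` with columns `percent`,
#'   `left_mean_N`, `left_sd_N`, `right_mean_N`, `right_sd_N`; attributes
#'   `n_cycles_averaged` and `fewer_than_requested`.
#' @export
normalize_and_average <- function(cycles, n_cycles = 15, grid_points = 101,
                                  selection = c("last", "first")) {
  selection <- match.arg(selection)
  if (!inherits(cycles, "stroke_cycles") || nrow(cycles) == 0) {
    kf_stop("`cycles` must be a non-empty stroke_cycles tibble.",
            "insufficient_data")
  }
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(grid_points, "grid_points", lower = 2)
  short <- nrow(cycles) < n_cycles
  if (short) {
    warn(sprintf("only %d cycles available; averaging all of them (%d requested).",
                 nrow(cycles), n_cycles))
    used <- cycles
  } else {
    n <- nrow(cycles)
    used <- cycles_slice(cycles, if (selection == "last")
      seq.int(n - n_cycles + 1, n) else seq_len(n_cycles))
  }
  grid <- seq(0, 100, length.out = grid_points)
  resample <- function(seg) {
    approx(seq(0, 100, length.out = length(seg)), seg, xout = grid)$y
  }
  lmat <- vapply(used$left, resample, numeric(grid_points))
  rmat <- vapply(used$right, resample, numeric(grid_points))
  sd0 <- function(m) if (ncol(m) > 1) apply(m, 1, sd) else rep(0, nrow(m))
  structure(tibble::tibble(
    percent = grid,
    left_mean_N = rowMeans(lmat), left_sd_N = sd0(lmat),
    right_mean_N = rowMeans(rmat), right_sd_N = sd0(rmat)
  ),
  n_cycles_averaged = nrow(used), fewer_than_requested = short,
  class = c("normalized_profile", class(tibble::tibble())))
}
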