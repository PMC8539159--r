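#' Specify a synthetic on-water paddling session
#'
#' Describes a bout of sprint-kayak paddling as seen by an instrumented
#' footrest: each leg pushes once per stroke cycle as a half-sine force
#' pulse riding on a residual baseline (the foot-strap pre-load), with the
#' left and right pulse trains offset by half a cycle. Stroke rate counts
#' both sides, so one full cycle (one left push plus one right push) is two
#' strokes and the per-push period is `60 / stroke_rate` seconds.
#'
#' @param duration Bout duration in seconds.
#' @param sampling_rate Sampling rate in Hz (default 1000, the rate of the
#'   load-cell acquisition this generator emulates).
#' @param stroke_rate Strokes per minute, counting each side's push as one
#'   stroke.
#' @param push_peak_left,push_peak_right Peak push force above zero for each
#'   side, in newtons. The half-sine pulse rises from the baseline to
#'   `baseline + push_peak` at its centre.
#' @param push_duty Fraction (0, 1] of each half-cycle occupied by the push
#'   pulse; the rest of the half-cycle sits at the baseline.
#' @param baseline Residual force in newtons when the leg is not pushing
#'   (feet strapped to the footrest keep the load cells slightly loaded).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   in newtons.
#' @param seed Integer seed for reproducibility.
#' @return A list of class `session_spec`.
#' @seealso [generate_force_session()]
#' @export
session_spec <- function(duration = 20, sampling_rate = 1000,
                         stroke_rate = 125, push_peak_left = 380,
                         push_peak_right = 380, push_duty = 0.75,
                         baseline = 20, noise_sd = 0, seed = NULL) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(stroke_rate, "stroke_rate", lower = 0, strict_lower = TRUE)
  check_number(push_duty, "push_duty", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(baseline, "baseline", lower = 0)
  check_number(push_peak_left, "push_peak_left", lower = 0)
  check_number(push_peak_right, "push_peak_right", lower = 0)
  spec <- list(
    duration = duration, sampling_rate = sampling_rate,
    stroke_rate = stroke_rate, push_peak_left = push_peak_left,
    push_peak_right = push_peak_right, push_duty = push_duty,
    baseline = baseline, noise_sd = noise_sd, seed = seed
  )
  structure(spec, class = "session_spec")
}

#' Generate a synthetic footrest force session with known ground truth
#'
#' Builds the two-channel force trace implied by a [session_spec()] and the
#' closed-form session truth that a correct preprocessing and feature
#' pipeline should recover: per-side peak forces and peak times, the
#' time-average force, the impulse per stroke cycle and per 10 s, and the
#' stroke rate. For a half-sine pulse of amplitude `P` (above baseline) and
#' width `w`, the per-pulse impulse above baseline is `2 P w / pi`.
#'
#' @param spec A [session_spec()].
#' @return A list with elements `trace` (a [force_trace()]) and `truth`
#'   (a list of class `session_truth`).
#' @examples
#' sess <- generate_force_session(session_spec(duration = 5, noise_sd = 0))
#' sess$truth$stroke_rate_spm
#' @export
generate_force_session <- function(spec) {
  if (!inherits(spec, "session_spec")) {
    kf_stop("`spec` must be a session_spec.", "validation")
  }
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  t_push <- 60 / spec$stroke_rate     # one side pushes every half cycle
  t_cycle <- 2 * t_push
  w <- spec$push_duty * t_push

  pulse_train <- function(peak, offset) {
    phase <- (t - offset) %% t_cycle
    in_push <- phase < w & t >= offset
    out <- numeric(n)
    out[in_push] <- peak * sin(pi * phase[in_push] / w)
    out
  }
  left <- spec$baseline + pulse_train(spec$push_peak_left, 0)
  right <- spec$baseline + pulse_train(spec$push_peak_right, t_push)

  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    left <- left + rnorm(n, 0, spec$noise_sd)
    right <- right + rnorm(n, 0, spec$noise_sd)
  }

  trace <- force_trace(
    tibble::tibble(time_s = t, left_N = left, right_N = right),
    sampling_rate = fs
  )

  peak_times <- function(offset) {
    centres <- seq(offset + w / 2, spec$duration, by = t_cycle)
    centres[centres + w / 2 <= spec$duration]
  }
  pulse_area <- 2 * w / pi  # per unit peak force, above baseline
  impulse_cycle <- 2 * spec$baseline * t_cycle +
    pulse_area * (spec$push_peak_left + spec$push_peak_right)
  truth <- structure(list(
    peak_left_N = spec$baseline + spec$push_peak_left,
    peak_right_N = spec$baseline + spec$push_peak_right,
    peak_force_N = spec$baseline +
      (spec$push_peak_left + spec$push_peak_right) / 2,
    mean_force_N = spec$baseline +
      pulse_area * (spec$push_peak_left + spec$push_peak_right) / (2 * t_cycle),
    impulse_cycle_Ns = impulse_cycle,
    impulse_10s_Ns = impulse_cycle * 10 / t_cycle,
    stroke_rate_spm = spec$stroke_rate,
    cycle_duration_s = t_cycle,
    push_width_s = w,
    peak_times_left_s = peak_times(0),
    peak_times_right_s = peak_times(t_push)
  ), class = "session_truth")

  list(trace = trace, truth = truth)
}

#' Generate a synthetic GPS velocity trace
#'
#' Emulates the velocity log of a bout with a rolling start: the boat ramps
#' linearly from a starting velocity to the target plateau over `ramp_time`
#' seconds, then holds the plateau; optional Gaussian noise is added on top
#' and the result clipped at zero.
#'
#' @param duration Trace duration in seconds (must exceed `ramp_time`).
#' @param target_velocity Plateau velocity in km/h.
#' @param ramp_time Ramp duration in seconds (>= 0).
#' @param noise_sd Gaussian noise SD in km/h.
#' @param seed Integer seed.
#' @param start_velocity Velocity at t = 0 in km/h; defaults to 70% of the
#'   target (a rolling, not standing, start).
#' @param sampling_rate Sampling rate in Hz; default 1 Hz, typical of a
#'   sports GPS watch.
#' @return A [velocity_trace()].
#' @export
generate_velocity_trace <- function(duration, target_velocity, ramp_time = 0,
                                    noise_sd = 0, seed = NULL,
                                    start_velocity = 0.7 * target_velocity,
                                    sampling_rate = 1) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(target_velocity, "target_velocity", lower = 0)
  check_number(ramp_time, "ramp_time", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(start_velocity, "start_velocity", lower = 0)
  if (ramp_time >= duration) {
    kf_stop("`ramp_time` must be smaller than `duration`.", "validation")
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  v <- if (ramp_time > 0) {
    pmin(start_velocity + (target_velocity - start_velocity) * t / ramp_time,
         target_velocity)
  } else {
    rep(target_velocity, n)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  velocity_trace(tibble::tibble(time_s = t, velocity_kmh = pmax(v, 0)))
}

#' Specify a synthetic paddler cohort
#'
#' Describes a cohort of paddler-bout feature records whose velocity/force
#' relationship is known exactly, for parameter-recovery testing of the
#' regression machinery. Two directions are supported:
#'
#' * `"velocity_on_features"`: named predictor features are drawn from
#'   independent normals (`predictor_means`, `predictor_sds`) and velocity is
#'   `intercept + sum(coefficients * features) + group offset + noise` —
#'   the structure of a maximal-velocity prediction model.
#' * `"feature_on_velocity"`: velocity is drawn uniformly on
#'   `velocity_range` and the single named feature is
#'   `intercept + slope * velocity + group offset + noise` — the structure
#'   of an explanatory (force-on-velocity) model.
#'
#' @param n_paddlers Number of records.
#' @param direction `"velocity_on_features"` or `"feature_on_velocity"`.
#' @param coefficients Named numeric vector. Names must be feature-table
#'   columns (`peak_force_N`, `impulse_10s_Ns`, `stroke_rate_spm`,
#'   `mean_force_N`, `impulse_cycle_Ns`); for `"feature_on_velocity"` exactly
#'   one coefficient (the slope of that feature on velocity).
#' @param intercept Model intercept (km/h or N / N·s depending on direction).
#' @param predictor_means,predictor_sds Named numeric vectors giving the
#'   sampling distribution of each predictor (direction
#'   `"velocity_on_features"`).
#' @param velocity_range Length-2 range of the uniform velocity draw
#'   (direction `"feature_on_velocity"`).
#' @param residual_sd Gaussian residual SD on the response.
#' @param groups Character vector of group labels to cycle through; defaults
#'   to the four age/sex groups.
#' @param group_offsets Named numeric vector of additive response offsets per
#'   group (default all zero).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_paddlers,
                        direction = c("velocity_on_features",
                                      "feature_on_velocity"),
                        coefficients, intercept,
                        predictor_means = NULL, predictor_sds = NULL,
                        velocity_range = c(12, 20), residual_sd = 0,
                        groups = kf_groups, group_offsets = NULL,
                        seed = NULL) {
  direction <- match.arg(direction)
  check_number(n_paddlers, "n_paddlers", lower = 1)
  check_number(residual_sd, "residual_sd", lower = 0)
  check_number(intercept, "intercept")
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    kf_stop("`coefficients` must be a fully named numeric vector.",
            "validation")
  }
  bad <- setdiff(names(coefficients),
                 setdiff(kf_feature_cols, "velocity_kmh"))
  if (length(bad)) {
    kf_stop(paste0("unknown predictor(s): ", paste(bad, collapse = ", ")),
            "validation")
  }
  if (direction == "feature_on_velocity" && length(coefficients) != 1L) {
    kf_stop("feature_on_velocity direction takes exactly one coefficient.",
            "validation")
  }
  if (direction == "velocity_on_features") {
    preds <- names(coefficients)
    if (!all(preds %in% names(predictor_means)) ||
        !all(preds %in% names(predictor_sds))) {
      kf_stop("`predictor_means` and `predictor_sds` must cover every coefficient.",
              "validation")
    }
    if (any(predictor_sds[preds] < 0)) {
      kf_stop("predictor SDs must be non-negative.", "validation")
    }
    if (length(preds) > 1 && any(predictor_sds[preds] == 0)) {
      kf_stop("zero predictor SD with more than one coefficient gives a singular design.",
              "validation")
    }
  }
  if (n_paddlers < length(coefficients) + 2) {
    kf_stop("`n_paddlers` must be at least the number of model parameters + 1.",
            "validation")
  }
  if (!is.null(group_offsets) &&
      !all(groups %in% names(group_offsets))) {
    kf_stop("`group_offsets` must name every group.", "validation")
  }
  structure(list(
    n_paddlers = as.integer(n_paddlers), direction = direction,
    coefficients = coefficients, intercept = intercept,
    predictor_means = predictor_means, predictor_sds = predictor_sds,
    velocity_range = velocity_range, residual_sd = residual_sd,
    groups = groups,
    group_offsets = group_offsets %||% setNames(rep(0, length(groups)), groups),
    seed = seed
  ), class = "cohort_spec")
}

# filler distributions for feature columns not driven by the cohort model;
# scale follows the maximal-effort regime of competitive sprint paddlers
kf_feature_fillers <- list(
  stroke_rate_spm = c(mean = 125, sd = 12),
  peak_force_N = c(mean = 398, sd = 106),
  mean_force_N = c(mean = 290, sd = 83),
  impulse_cycle_Ns = c(mean = 555, sd = 17),
  impulse_10s_Ns = c(mean = 2384, sd = 87)
)

#' Generate a synthetic paddler cohort with known regression truth
#'
#' Draws the feature table implied by a [cohort_spec()]. Feature columns not
#' involved in the cohort's linear model are filled with independent draws
#' on a realistic scale (truncated at zero) so that the table is a complete
#' feature record. The generating parameters are stored in the `truth`
#' attribute for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of feature records (one row per paddler-bout) with
#'   attribute `truth` (list: `direction`, `coefficients`, `intercept`,
#'   `residual_sd`, `group_offsets`).
#' @examples
#' spec <- cohort_spec(
#'   n_paddlers = 25, direction = "velocity_on_features",
#'   coefficients = c(peak_force_N = 0.0045, impulse_10s_Ns = 0.0017,
#'                    stroke_rate_spm = 0.05),
#'   intercept = 7.62,
#'   predictor_means = c(peak_force_N = 398, impulse_10s_Ns = 2384,
#'                       stroke_rate_spm = 125),
#'   predictor_sds = c(peak_force_N = 106, impulse_10s_Ns = 87,
#'                     stroke_rate_spm = 12),
#'   residual_sd = 0.5, seed = 42
#' )
#' cohort <- generate_cohort(spec)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    kf_stop("`spec` must be a cohort_spec.", "validation")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_paddlers
  group <- rep_len(spec$groups, n)
  offsets <- spec$group_offsets[group]

  features <- setdiff(kf_feature_cols, "velocity_kmh")
  tab <- tibble::tibble(
    paddler_id = sprintf("P%03d", seq_len(n)),
    group = group,
    bout = "maximal"
  )

  if (spec$direction == "velocity_on_features") {
    preds <- names(spec$coefficients)
    for (p in features) {
      if (p %in% preds) {
        tab[[p]] <- rnorm(n, spec$predictor_means[[p]], spec$predictor_sds[[p]])
      } else {
        f <- kf_feature_fillers[[p]]
        tab[[p]] <- pmax(rnorm(n, f[["mean"]], f[["sd"]]), 0)
      }
    }
    lin <- as.matrix(tab[preds]) %*% spec$coefficients
    tab$velocity_kmh <- spec$intercept + drop(lin) + offsets +
      rnorm(n, 0, spec$residual_sd)
  } else {
    target <- names(spec$coefficients)
    tab$velocity_kmh <- runif(n, spec$velocity_range[1], spec$velocity_range[2])
    for (p in setdiff(features, target)) {
      f <- kf_feature_fillers[[p]]
      tab[[p]] <- pmax(rnorm(n, f[["mean"]], f[["sd"]]), 0)
    }
    tab[[target]] <- spec$intercept +
      spec$coefficients[[1]] * tab$velocity_kmh + offsets +
      rnorm(n, 0, spec$residual_sd)
  }

  tab <- tab[c("paddler_id", "group", "bout", kf_feature_cols)]
  attr(tab, "truth") <- list(
    direction = spec$direction, coefficients = spec$coefficients,
    intercept = spec$intercept, residual_sd = spec$residual_sd,
    group_offsets = spec$group_offsets
  )
  tab
}
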