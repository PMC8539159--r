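# shared fixtures, built in code

# a clean 20-s maximal-effort-like session (on-grid pulse timing at 1000 Hz)
quick_session <- function(duration = 20, stroke_rate = 125, noise_sd = 0,
                          seed = NULL, push_peak_left = 380,
                          push_peak_right = 360, baseline = 20,
                          sampling_rate = 1000) {
  generate_force_session(session_spec(
    duration = duration, sampling_rate = sampling_rate,
    stroke_rate = stroke_rate, push_peak_left = push_peak_left,
    push_peak_right = push_peak_right, push_duty = 0.75,
    baseline = baseline, noise_sd = noise_sd, seed = seed
  ))
}

# cohort generated from the published maximal-velocity coefficient vector
eq1_cohort_spec <- function(n, residual_sd, seed) {
  cohort_spec(
    n_paddlers = n, direction = "velocity_on_features",
    coefficients = c(peak_force_N = 0.0045, impulse_10s_Ns = 0.0017,
                     stroke_rate_spm = 0.05),
    intercept = 7.62,
    predictor_means = c(peak_force_N = 398, impulse_10s_Ns = 2384,
                        stroke_rate_spm = 125),
    predictor_sds = c(peak_force_N = 106, impulse_10s_Ns = 87,
                      stroke_rate_spm = 12),
    residual_sd = residual_sd, seed = seed
  )
}

eq1_predictors <- c("peak_force_N", "impulse_10s_Ns", "stroke_rate_spm")

feature_cols <- c("velocity_kmh", "stroke_rate_spm", "mean_force_N",
                  "peak_force_N", "impulse_cycle_Ns", "impulse_10s_Ns")

# independent fine-grid Riemann-sum integral (midpoint rule) of a sampled
# signal, for checking trapezoid impulses without using pracma
riemann_oracle <- function(t, y, refine = 20) {
  tf <- seq(t[1], t[length(t)], length.out = refine * length(t))
  yf <- approx(t, y, xout = tf)$y
  mid <- (yf[-1] + yf[-length(yf)]) / 2
  sum(mid * diff(tf))
}

# a force trace with constant values on both channels
constant_trace <- function(value = 100, duration = 5, fs = 1000) {
  n <- duration * fs
  force_trace(tibble::tibble(
    time_s = (0:(n - 1)) / fs,
    left_N = rep(value, n), right_N = rep(value, n)
  ))
}
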