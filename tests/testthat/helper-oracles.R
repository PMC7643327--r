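# Independent oracles and small generators used across the suite.

# Brute-force trapezoidal integration of |D - d| over the first complete
# epoch(s), averaged — deliberately a different discretization from the
# package's rectangle sum, to bound discretization error.
trapezoid_index <- function(trace, epoch_ms = 3000) {
  dt <- attr(trace, "line_period_ms")
  n_per <- floor(epoch_ms / dt)
  n_epochs <- floor(nrow(trace) / n_per)
  f <- abs(trace$D_um - trace$d_um)
  vals <- vapply(seq_len(n_epochs), function(e) {
    idx <- ((e - 1) * n_per + 1):(e * n_per)
    y <- f[idx]
    sum((y[-1] + y[-length(y)]) / 2) * dt
  }, numeric(1))
  mean(vals)
}

# Normal-equations OLS, independent of stats::lm.
normal_eq_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Random smooth diameter trace: baseline + a few sinusoids, with its
# moving-average baseline attached. The default length is a whole number of
# 3000-ms epochs so epoch-symmetric properties (e.g. time reversal) apply.
random_trace <- function(seed, n = 6000, dt = 1, window_ms = 500) {
  set.seed(seed)
  t_ms <- (seq_len(n) - 1) * dt
  base <- runif(1, 6, 20)
  D <- base
  for (k in seq_len(sample(1:3, 1))) {
    D <- D + runif(1, 0.1, 1) * sin(2 * pi * runif(1, 3, 10) * t_ms / 1000 +
                                    runif(1, 0, 2 * pi))
  }
  tr <- diameter_trace(t_ms, D, line_period_ms = dt)
  moving_average_baseline(tr, window_ms = window_ms)
}

# A small noiseless sinusoidal kymograph spec used in several places.
sinus_spec <- function(amplitude = 1, noise = NULL, seed = 1,
                       duration_ms = 3000, freq = 5) {
  kymograph_spec(
    baseline_diameter_um = 10, pulse_amplitude_um = amplitude,
    pulse_frequency_hz = freq, duration_ms = duration_ms,
    line_period_ms = 1, pixel_size_um = 0.25, wall_blur_sigma_px = 1,
    noise = noise, seed = seed
  )
}
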