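# Independent oracles and small fixture builders shared across test files.

# brute-force percentile: sort and linearly interpolate between order
# statistics (inclusive), written without stats::quantile on purpose
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# direct trailing-window mean, the O(n*w) definition of the running average
oracle_trailing_mean <- function(z, w) {
  vapply(seq_along(z), function(i) mean(z[max(1L, i - w + 1L):i]), numeric(1))
}

# plain sinusoidal trace: baseline + a * sin(2 pi t / period), 100 Hz
sinusoid_trace <- function(duration_s = 60, period_s = 5, a = 5,
                           baseline = 100, rate_hz = 100) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  impedance_trace(t, baseline + a * sin(2 * pi * t / period_s), rate_hz = rate_hz)
}

# minimal cycle table for exercising compare_cycles / vae_score directly
fake_cycles <- function(p25, p75, period_s = 5, valid = TRUE) {
  n <- length(p25)
  df <- tibble::tibble(
    t_start = (seq_len(n) - 1) * period_s,
    t_end = seq_len(n) * period_s,
    t_peak = (seq_len(n) - 0.5) * period_s,
    z_min = p25 - 1, z_max = p75 + 1,
    z_p25 = p25, z_p75 = p75,
    n_samples = rep(100L, n)
  )
  attr(df, "rate_bpm") <- 60 / period_s
  attr(df, "valid") <- valid
  attr(df, "peaks") <- df$t_peak
  class(df) <- c("resp_cycles", class(tibble::tibble()))
  df
}

fake_sqi <- function(value) {
  tibble::tibble(value = value, c_presence = value, c_regularity = value,
                 c_amplitude = value, c_robustness = value, c_consistency = value)
}
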