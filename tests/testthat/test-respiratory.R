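test_that("trailing running average matches its direct definition", {
  const <- impedance_trace((0:999) / 100, rep(7, 1000))
  sm <- smooth_trace(const, 0.5)
  expect_true(all(sm$impedance_ohm == 7))

  # unit step: boxcar of a step is a linear ramp over one window
  t <- (0:1999) / 100
  step <- impedance_trace(t, as.numeric(t >= 10))
  sm <- smooth_trace(step, 1)
  in_ramp <- t > 10 & t < 11
  expect_equal(sm$impedance_ohm[in_ramp],
               (t[in_ramp] - 10 + 0.01) / 1, tolerance = 1e-10)
  expect_true(all(sm$impedance_ohm[t >= 11] == 1))

  # sinusoid: compare against the O(n*w) trailing-mean oracle
  tr <- sinusoid_trace(20, period_s = 5, a = 5)
  sm <- smooth_trace(tr, 0.5)
  expect_equal(sm$impedance_ohm, oracle_trailing_mean(tr$impedance_ohm, 50),
               tolerance = 1e-9)
  expect_equal(trace_meta(sm)$warmup_s, 0.5)
})

test_that("smoothing rejects degenerate configurations", {
  tr <- sinusoid_trace(5)
  expect_error(smooth_trace(tr, 10), "invalid configuration")
  expect_error(smooth_trace(tr, -1), "invalid configuration")
})

test_that("wavelet detection finds one peak per breath", {
  tr <- sinusoid_trace(60, period_s = 5, a = 5)
  pk <- detect_peaks(tr)
  expect_length(pk, 12)
  # sinusoid maxima sit at 1.25, 6.25, ...; 1-sample slack
  expect_equal(pk, seq(1.25, 56.25, by = 5), tolerance = 0.011)

  const <- impedance_trace((0:5999) / 100, rep(100, 6000))
  expect_length(detect_peaks(const), 0)

  # additive noise moves no peak by more than 0.25 s relative to the same
  # pipeline (smoothing included — the causal window lags both equally)
  set.seed(7)
  noisy <- impedance_trace(tr$time_s, tr$impedance_ohm + rnorm(6000, 0, 0.5))
  pkn <- detect_peaks(smooth_trace(noisy, 0.5))
  pkc <- detect_peaks(smooth_trace(tr, 0.5))
  expect_length(pkn, 12)
  expect_true(all(abs(pkn - pkc) <= 0.25))
})

test_that("rate validation enforces the 6-30 bpm ventilation band", {
  v <- validate_rate(seq(0, 55, by = 5))
  expect_true(v$valid)
  expect_equal(v$rate_bpm, 12)

  expect_false(validate_rate(seq(0, 20, by = 1))$valid)   # 60 bpm
  expect_false(validate_rate(seq(0, 60, by = 12))$valid)  # 5 bpm
  expect_false(validate_rate(c(0, 5))$valid)              # too few peaks
  # irregular intervals fail the MAD gate even with an in-band median
  expect_false(validate_rate(c(0, 3, 10, 12, 21, 24))$valid)
})

test_that("cycle summaries match a brute-force percentile oracle", {
  sim <- simulate_trace(duration_s = 90, noise_sigma_ohm = 0.5, seed = 42)
  cfg <- vae_config()
  sm <- smooth_trace(sim$trace, cfg$smoothing$window_s)
  cyc <- respiratory_cycles(sim$trace, cfg)
  expect_true(cycles_valid(cyc))
  expect_gt(nrow(cyc), 10)
  for (i in seq_len(nrow(cyc))) {
    zz <- sm$impedance_ohm[sm$time_s >= cyc$t_start[i] - 1e-9 &
                             sm$time_s < cyc$t_end[i] - 1e-9]
    expect_equal(cyc$n_samples[i], length(zz))
    expect_equal(cyc$z_min[i], min(zz))
    expect_equal(cyc$z_max[i], max(zz))
    expect_equal(cyc$z_p25[i], oracle_percentile(zz, 0.25), tolerance = 1e-12)
    expect_equal(cyc$z_p75[i], oracle_percentile(zz, 0.75), tolerance = 1e-12)
  }
})

test_that("cycles are ordered, non-overlapping and internally consistent", {
  sim <- simulate_trace(duration_s = 90, seed = 9)
  cyc <- respiratory_cycles(sim$trace)
  expect_true(all(diff(cyc$t_start) > 0))
  expect_equal(cyc$t_start[-1], cyc$t_end[-nrow(cyc)]) # tiling
  expect_true(all(cyc$t_start < cyc$t_peak & cyc$t_peak <= cyc$t_end))
  expect_true(all(cyc$z_min <= cyc$z_p25 & cyc$z_p25 <= cyc$z_p75 &
                    cyc$z_p75 <= cyc$z_max))
  expect_true(all(cyc$t_end - cyc$t_start >= 2 & cyc$t_end - cyc$t_start <= 10))
})

test_that("cycle summaries are translation-equivariant", {
  sim <- simulate_trace(duration_s = 60, noise_sigma_ohm = 0.3, seed = 5)
  shifted <- impedance_trace(sim$trace$time_s, sim$trace$impedance_ohm + 5)
  a <- respiratory_cycles(sim$trace)
  b <- respiratory_cycles(shifted)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$z_p25, a$z_p25 + 5, tolerance = 1e-9)
  expect_equal(b$z_p75, a$z_p75 + 5, tolerance = 1e-9)
  expect_equal(b$z_min, a$z_min + 5, tolerance = 1e-9)
  expect_equal(b$z_max, a$z_max + 5, tolerance = 1e-9)
  expect_equal(b$t_peak, a$t_peak)
})

test_that("band-passed noise is not mistaken for ventilation", {
  sim <- simulate_trace(duration_s = 60, resp_rate_bpm = 0, noise_sigma_ohm = 1,
                        seed = 3)
  cyc <- respiratory_cycles(sim$trace)
  expect_false(cycles_valid(cyc))
  expect_equal(nrow(cyc), 0)
})
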