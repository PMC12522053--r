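test_that("cycle deltas classify ventilator maneuvers versus paired rises", {
  base <- rep(250, 6)
  top <- rep(257, 6)
  expect_true(all(compare_cycles(fake_cycles(base, top))$classification == "stable"))

  d <- compare_cycles(fake_cycles(base, c(top[1:3], top[4:6] + 2)))
  expect_equal(d$classification[3], "tv_change")
  expect_equal(d$d_eii[3], 2)
  expect_equal(d$d_eei[3], 0)

  d <- compare_cycles(fake_cycles(cumsum(c(250, rep(0.5, 5))),
                                  cumsum(c(257, rep(0.5, 5)))))
  expect_true(all(d$classification == "vae_or_peep"))

  d <- compare_cycles(fake_cycles(c(base[1:3], base[4:6] + 1), top))
  expect_equal(d$classification[3], "peep_tv_edge")

  expect_equal(nrow(compare_cycles(fake_cycles(250, 257))), 0)
})

test_that("blips are recovered with accurate onset and duration", {
  sim <- simulate_trace(duration_s = 60, seed = 8,
                        events = list(sim_event("blip", t_start = 30.2,
                                                duration_s = 1, magnitude = 14)))
  cyc <- respiratory_cycles(sim$trace)
  b <- detect_blips(sim$trace, cyc)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$t_onset - 30.2), 0.021) # within 2 samples at 100 Hz
  expect_gt(b$duration_s, 0.8)
  expect_lt(b$duration_s, 1.4)
  expect_gt(b$amplitude_ohm, 14 * 0.85)
  expect_lt(b$amplitude_ohm, 14 + 7 + 1) # bolus plus at most one breath crest

  expect_equal(nrow(detect_blips(simulate_trace(duration_s = 60, seed = 9)$trace,
                                 respiratory_cycles(simulate_trace(duration_s = 60, seed = 9)$trace))),
               0)
})

test_that("sustained excursions are routed away from the blip path", {
  sim <- simulate_trace(duration_s = 60, seed = 21,
                        events = list(sim_event("baseline_step", 25, 1, 15),
                                      sim_event("baseline_step", 33, 1, -15)))
  b <- detect_blips(sim$trace, respiratory_cycles(sim$trace))
  expect_equal(nrow(b), 0)
})

test_that("absolute-rise path responds to sustained unventilated rises only", {
  flat <- simulate_trace(duration_s = 60, resp_rate_bpm = 0,
                         noise_sigma_ohm = 0.05, seed = 10)
  cyc <- respiratory_cycles(flat$trace)
  expect_false(cycles_valid(cyc))
  expect_lt(detect_absolute_rise(flat$trace, cyc)$component, 10)

  stepped <- simulate_trace(duration_s = 60, resp_rate_bpm = 0,
                            noise_sigma_ohm = 0.05, seed = 10,
                            events = list(sim_event("baseline_step", 30, 1, 2)))
  cycs <- respiratory_cycles(stepped$trace)
  res <- detect_absolute_rise(stepped$trace, cycs)
  expect_gte(res$component, 50)
  expect_equal(res$rise_ohm, 2, tolerance = 0.1)

  # a half-second excursion is a blip, not an absolute rise
  pulsed <- simulate_trace(duration_s = 60, resp_rate_bpm = 0,
                           noise_sigma_ohm = 0.05, seed = 10,
                           events = list(sim_event("blip", 50, 0.5, 2)))
  cycp <- respiratory_cycles(pulsed$trace)
  expect_lt(detect_absolute_rise(pulsed$trace, cycp)$component, 50)
  bp <- detect_blips(pulsed$trace, cycp)
  expect_equal(nrow(bp), 1)
  expect_lt(abs(bp$t_onset - 50), 0.05)
})

test_that("score combination starts at zero and respects the SQI gate", {
  cfg <- vae_config()
  cyc <- fake_cycles(rep(250, 4), rep(257, 4))
  none <- compare_cycles(cyc)
  no_blips <- tibble::tibble(t_onset = numeric(0), t_offset = numeric(0),
                             duration_s = numeric(0), amplitude_ohm = numeric(0))
  sc <- vae_score(none, no_blips, 0, fake_sqi(0.95), cyc, cfg)
  expect_equal(sc$score, 0)
  expect_false(sc$alarm_raw)
  expect_false(sc$suppressed_low_sqi)

  # strong blip evidence with poor signal quality: suppressed, flagged
  blips <- tibble::tibble(t_onset = 10, t_offset = 11, duration_s = 1,
                          amplitude_ohm = 20)
  hi <- vae_score(none, blips, 0, fake_sqi(0.9), cyc, cfg)
  expect_gte(hi$score, cfg$detection$alarm_threshold)
  expect_true(hi$alarm_raw)
  lo <- vae_score(none, blips, 0, fake_sqi(0.1), cyc, cfg)
  expect_equal(lo$score, hi$score)
  expect_false(lo$alarm_raw)
  expect_true(lo$suppressed_low_sqi)

  # the absolute path overrides the gate: it exists for signals whose SQI
  # is necessarily poor (no ventilation present)
  inv <- fake_cycles(rep(250, 4), rep(257, 4), valid = FALSE)
  ab <- vae_score(none[0, ], blips[0, ], 80, fake_sqi(0.05), inv, cfg)
  expect_true(ab$alarm_raw)
  expect_equal(ab$absolute_component, 80)
})

test_that("trend evidence accumulates over consecutive paired rises", {
  cfg <- vae_config()
  no_blips <- tibble::tibble(t_onset = numeric(0), t_offset = numeric(0),
                             duration_s = numeric(0), amplitude_ohm = numeric(0))
  cyc <- fake_cycles(cumsum(c(250, rep(0.2, 6))), cumsum(c(257, rep(0.2, 6))))
  d <- compare_cycles(cyc, cfg$detection$tau_ohm)
  sc <- vae_score(d, no_blips, 0, fake_sqi(0.95), cyc, cfg)
  expect_equal(sc$trend_run, 6)
  expect_equal(sc$trend_rise_ohm, 1.2, tolerance = 1e-9)
  expect_gte(sc$trend_component, cfg$detection$alarm_threshold)
  expect_true(sc$alarm_raw)

  # a single ventilated paired step (e.g. PEEP-sized) also alarms
  cyc1 <- fake_cycles(c(250, 250, 252, 252), c(257, 257, 259, 259))
  d1 <- compare_cycles(cyc1, cfg$detection$tau_ohm)
  sc1 <- vae_score(d1, no_blips, 0, fake_sqi(0.95), cyc1, cfg)
  expect_gte(sc1$trend_component, cfg$detection$alarm_threshold)
})

test_that("peak score never decreases with ramp slope", {
  peak_score <- function(mag) {
    sim <- simulate_trace(duration_s = 120, noise_sigma_ohm = 0.2, seed = 77,
                          events = list(sim_event("ramp", t_start = 45,
                                                  duration_s = 60, magnitude = mag)))
    max(analyze_trace(sim$trace)$score)
  }
  scores <- vapply(c(0.5, 1, 2, 4), peak_score, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("a sustained step alarms through the path matching ventilation state", {
  # ventilated: the step is cycle-comparable, so the trend path carries it
  vent <- simulate_trace(duration_s = 120, seed = 31,
                         events = list(sim_event("baseline_step", 60, 1, 2)))
  av <- analyze_trace(vent$trace)
  expect_true(any(av$alarm))
  w <- which(av$alarm_raw)[1]
  expect_gte(av$trend_component[w], 50)
  expect_equal(av$absolute_component[w], 0)

  # apnoeic: no cycles to compare, the absolute path carries it
  apn <- simulate_trace(duration_s = 120, resp_rate_bpm = 0,
                        noise_sigma_ohm = 0.05, seed = 31,
                        events = list(sim_event("baseline_step", 60, 1, 2)))
  aa <- analyze_trace(apn$trace)
  expect_true(any(aa$alarm))
  wa <- which(aa$alarm_raw)[1]
  expect_gte(aa$absolute_component[wa], 50)
  expect_false(aa$valid[wa])
})
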