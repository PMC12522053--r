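test_that("the generator is a pure function of its configuration and seed", {
  a <- simulate_trace(duration_s = 30, seed = 99,
                      events = list(sim_event("blip", 15, 1, 10)))
  b <- simulate_trace(duration_s = 30, seed = 99,
                      events = list(sim_event("blip", 15, 1, 10)))
  expect_identical(a$trace$impedance_ohm, b$trace$impedance_ohm)
  expect_identical(a$decomposition, b$decomposition)
  expect_false(identical(
    a$trace$impedance_ohm,
    simulate_trace(duration_s = 30, seed = 100,
                   events = list(sim_event("blip", 15, 1, 10)))$trace$impedance_ohm
  ))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(simulate_trace(duration_s = 10, seed = 12345))
  expect_identical(rnorm(1), before)
})

test_that("confounders touch only their own decomposition term", {
  ref <- simulate_trace(duration_s = 60, seed = 7)
  tv <- simulate_trace(duration_s = 60, seed = 7,
                       events = list(sim_event("tv_step", 30, 30, 1.3)))
  expect_identical(tv$decomposition$baseline, ref$decomposition$baseline)
  expect_identical(tv$decomposition$event, ref$decomposition$event)
  expect_identical(tv$decomposition$noise, ref$decomposition$noise)
  pre <- tv$decomposition$time_s < 30
  expect_identical(tv$decomposition$carrier[pre], ref$decomposition$carrier[pre])
  expect_equal(tv$decomposition$carrier[!pre],
               1.3 * ref$decomposition$carrier[!pre], tolerance = 1e-12)

  st <- simulate_trace(duration_s = 60, seed = 7,
                       events = list(sim_event("baseline_step", 30, 1, 2)))
  expect_identical(st$decomposition$carrier, ref$decomposition$carrier)
  expect_identical(st$decomposition$noise, ref$decomposition$noise)
  expect_true(all(st$decomposition$event[st$decomposition$time_s < 30] == 0))
  expect_true(all(abs(st$decomposition$event[st$decomposition$time_s > 32] - 2) < 1e-12))
})

test_that("ground truth records every event with its exact timing", {
  sim <- simulate_trace(duration_s = 60, seed = 2,
                        events = list(sim_event("blip", 12.5, 0.8, 14),
                                      sim_event("ramp", 30, 20, 1)))
  expect_equal(nrow(sim$truth), 2)
  expect_equal(sim$truth$t_start, c(12.5, 30))
  expect_equal(sim$truth$t_end, c(13.3, 50))
  expect_equal(sim$truth$magnitude, c(14, 1))
})

test_that("contradictory overlapping events are rejected", {
  expect_error(
    simulate_trace(duration_s = 60, seed = 1,
                   events = list(sim_event("apnea_interval", 20, 20),
                                 sim_event("tv_step", 25, 30, 1.3))),
    "configuration error"
  )
  expect_error(sim_event("blip", 10, duration_s = 8), "blip duration")
  expect_error(
    simulate_trace(duration_s = 10, events = list(sim_event("blip", 50, 1, 5))),
    "after trace end"
  )
})

test_that("a stationary noise-free signal yields identical cycle summaries", {
  sim <- simulate_trace(duration_s = 60, noise_sigma_ohm = 0, seed = 1)
  cyc <- respiratory_cycles(sim$trace)
  expect_gte(nrow(cyc), 9)
  expect_lt(diff(range(cyc$z_p25)), 1e-6)
  expect_lt(diff(range(cyc$z_p75)), 1e-6)
  expect_lt(diff(range(cyc$z_min)), 1e-6)
  expect_lt(diff(range(cyc$z_max)), 1e-6)
})

test_that("tidal-volume and baseline steps move the summaries they should", {
  tv <- simulate_trace(duration_s = 120, noise_sigma_ohm = 0.05, seed = 13,
                       events = list(sim_event("tv_step", 60, 60, 1.3)))
  cyc <- respiratory_cycles(tv$trace)
  pre <- cyc[cyc$t_end < 58, ]
  post <- cyc[cyc$t_start > 62, ]
  expect_gt(mean(post$z_p75) - mean(pre$z_p75), 1)   # EII follows amplitude
  expect_lt(abs(mean(post$z_p25) - mean(pre$z_p25)), 0.1) # EEI does not

  bs <- simulate_trace(duration_s = 120, noise_sigma_ohm = 0.05, seed = 13,
                       events = list(sim_event("baseline_step", 60, 1, 2)))
  cycb <- respiratory_cycles(bs$trace)
  preb <- cycb[cycb$t_end < 58, ]
  postb <- cycb[cycb$t_start > 62, ]
  expect_equal(mean(postb$z_p25) - mean(preb$z_p25), 2, tolerance = 0.1)
  expect_equal(mean(postb$z_p75) - mean(preb$z_p75), 2, tolerance = 0.1)
})

test_that("irregular hand ventilation lowers signal quality", {
  clean <- simulate_trace(duration_s = 90, seed = 14)
  irr <- simulate_trace(duration_s = 90, seed = 14,
                        events = list(sim_event("irregular_ventilation", 0, 90, 0.25)))
  sq <- function(sim) compute_sqi(sim$trace, respiratory_cycles(sim$trace))$value
  expect_gt(sq(clean), sq(irr))
})

test_that("fixture suite regeneration is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 5, duration_s = 40)
  f2 <- make_fixture_suite(d2, seed = 5, duration_s = 40)
  expect_equal(nrow(f1), 11)
  for (i in seq_len(nrow(f1))) {
    expect_identical(readLines(f1$trace_path[i]), readLines(f2$trace_path[i]))
    expect_identical(readLines(f1$truth_path[i]), readLines(f2$truth_path[i]))
  }
  back <- read_trace(f1$trace_path[1])
  expect_equal(trace_rate(back), 100)
  expect_gt(nrow(back), 0)
})
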