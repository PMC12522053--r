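#' Declare an event for the waveform simulator
#'
#' @param kind One of `"blip"` (smoothed rectangular bolus pulse), `"ramp"`
#'   (linear rise over `duration_s`, then held — gradual entrainment),
#'   `"baseline_step"` (sustained additive step), `"tv_step"` (multiplies
#'   the respiratory carrier amplitude by `magnitude` from `t_start` on;
#'   moves only the end-inspiratory level), `"peep_step"` (additive step —
#'   like a PEEP increase it moves EEI and EII together), `"cautery_burst"`
#'   (interval of 20x-amplified noise), `"irregular_ventilation"` (per-breath
#'   period/amplitude jitter over the interval), `"apnea_interval"` (carrier
#'   zeroed over the interval).
#' @param t_start Event onset in seconds.
#' @param duration_s Event duration in seconds (blips default to brief;
#'   steps extend to trace end regardless).
#' @param magnitude Ohms for additive events; a multiplicative factor for
#'   `tv_step`; jitter fraction for `irregular_ventilation` (default 0.2);
#'   ignored for `apnea_interval`.
#' @param rise_s Edge rise time for blips and steps, seconds.
#' @return A `sim_event` list.
#' @export
sim_event <- function(kind, t_start, duration_s = 1, magnitude = 1, rise_s = 0.04) {
  kinds <- c("blip", "ramp", "baseline_step", "tv_step", "peep_step",
             "cautery_burst", "irregular_ventilation", "apnea_interval")
  kind <- match.arg(kind, kinds)
  if (!is.numeric(t_start) || t_start < 0) stop("`t_start` must be >= 0", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s < 0) stop("`duration_s` must be >= 0", call. = FALSE)
  if (kind == "blip" && duration_s > 5) {
    stop("blip duration must be <= 5 s (longer events are ramps or steps)", call. = FALSE)
  }
  structure(list(kind = kind, t_start = t_start, duration_s = duration_s,
                 magnitude = magnitude, rise_s = rise_s),
            class = "sim_event")
}

#' Simulate a mechanically ventilated chest impedance trace
#'
#' Generates `baseline + respiratory carrier + events + Gaussian noise` with
#' a ground-truth event log and the noise-free additive decomposition, so
#' detector tests can key off exact injected timings rather than
#' re-detection. The respiratory carrier spans `resp_amplitude_ohm` peak to
#' peak above the end-expiratory baseline; the default 7 ohms sits mid-way
#' through the 5-10 ohm excursion typical of surgical ventilation, on a
#' 250 ohm baseline. The default `"skewed"` carrier mimics mechanical
#' ventilation: a raised-cosine inspiration over 35% of the cycle, a
#' raised-cosine expiration over 25%, then an end-expiratory pause at the
#' baseline for the final 40% (an I:E ratio near 1:2, with passive
#' exhalation faster than insufflation). The pause matters: because more than a
#' quarter of each cycle rests at the end-expiratory level, the 25th
#' percentile tracks that level and a tidal-volume (amplitude) change moves
#' only the end-inspiratory summary, as the detector's confounder
#' discrimination assumes. `"sinusoid"` is available for analytic tests.
#' Identical configuration and seed give an identical trace.
#'
#' @param duration_s Trace length in seconds.
#' @param rate_hz Sample rate (default 100 Hz).
#' @param baseline_ohm End-expiratory baseline impedance.
#' @param resp_rate_bpm Ventilation rate in breaths per minute; 0 simulates
#'   apnoea (no carrier).
#' @param resp_amplitude_ohm Peak-to-peak respiratory excursion in ohms.
#' @param resp_shape `"skewed"` or `"sinusoid"`.
#' @param noise_sigma_ohm Additive white Gaussian noise sigma.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param events List of [sim_event()]s.
#' @return A list of class `vae_simulation`: `trace` (an
#'   [impedance_trace()]), `truth` (tibble of events with exact onsets and
#'   offsets), and `decomposition` (tibble with the noise-free `baseline`,
#'   `carrier`, `event` and `noise` terms per sample).
#' @export
simulate_trace <- function(duration_s = 60, rate_hz = 100, baseline_ohm = 250,
                           resp_rate_bpm = 12, resp_amplitude_ohm = 7,
                           resp_shape = c("skewed", "sinusoid"),
                           noise_sigma_ohm = 0.1, seed = 1, events = list()) {
  resp_shape <- match.arg(resp_shape)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (resp_rate_bpm < 0 || resp_rate_bpm > 60) {
    stop("`resp_rate_bpm` must be in [0, 60]", call. = FALSE)
  }
  if (resp_amplitude_ohm < 0 || noise_sigma_ohm < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (inherits(events, "sim_event")) events <- list(events)
  for (ev in events) {
    if (!inherits(ev, "sim_event")) stop("`events` must be sim_event objects", call. = FALSE)
    if (ev$t_start > duration_s) {
      stop("event starts after trace end: ", ev$kind, call. = FALSE)
    }
  }
  check_event_conflicts(events)

  n <- as.integer(round(duration_s * rate_hz))
  t <- (seq_len(n) - 1) / rate_hz

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # per-breath schedule (period/amplitude multipliers; jittered inside
  # irregular_ventilation intervals)
  irr <- Filter(function(e) e$kind == "irregular_ventilation", events)
  amp_mult <- function(tt) { # tv_step multiplies the carrier only
    m <- rep(1, length(tt))
    for (ev in events) {
      if (ev$kind == "tv_step") m[tt >= ev$t_start] <- ev$magnitude
    }
    m
  }
  carrier <- numeric(n)
  if (resp_rate_bpm > 0 && resp_amplitude_ohm > 0) {
    period <- 60 / resp_rate_bpm
    t0 <- 0
    while (t0 < duration_s) {
      p_i <- period
      a_i <- 1
      for (ev in irr) {
        if (t0 >= ev$t_start && t0 < ev$t_start + ev$duration_s) {
          jf <- if (ev$magnitude > 0) ev$magnitude else 0.2
          p_i <- period * exp(stats::rnorm(1, 0, jf))
          a_i <- max(0.2, 1 + stats::rnorm(1, 0, jf))
        }
      }
      idx <- which(t >= t0 & t < t0 + p_i)
      if (length(idx)) {
        phi <- (t[idx] - t0) / p_i
        s <- if (resp_shape == "sinusoid") {
          0.5 * (1 - cos(2 * pi * phi))
        } else {
          # inspiration 35%, expiration 25%, end-expiratory pause 40%
          ifelse(phi < 0.35, 0.5 * (1 - cos(pi * phi / 0.35)),
                 ifelse(phi < 0.6, 0.5 * (1 + cos(pi * (phi - 0.35) / 0.25)), 0))
        }
        carrier[idx] <- resp_amplitude_ohm * a_i * s
      }
      t0 <- t0 + p_i
    }
    carrier <- carrier * amp_mult(t)
    for (ev in events) {
      if (ev$kind == "apnea_interval") {
        carrier[t >= ev$t_start & t < ev$t_start + ev$duration_s] <- 0
      }
    }
  }

  event_term <- numeric(n)
  noise <- if (noise_sigma_ohm > 0) stats::rnorm(n, 0, noise_sigma_ohm) else numeric(n)
  smoothstep <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  truth_rows <- list()
  for (ev in events) {
    add <- numeric(n)
    t_end <- ev$t_start + ev$duration_s
    if (ev$kind == "blip") {
      up <- smoothstep((t - ev$t_start) / ev$rise_s)
      dn <- smoothstep((t - t_end) / ev$rise_s)
      add <- ev$magnitude * (up - dn)
    } else if (ev$kind == "ramp") {
      add <- ev$magnitude * pmin(1, pmax(0, (t - ev$t_start) / ev$duration_s))
    } else if (ev$kind %in% c("baseline_step", "peep_step")) {
      add <- ev$magnitude * smoothstep((t - ev$t_start) / ev$rise_s)
    } else if (ev$kind == "cautery_burst") {
      in_ev <- t >= ev$t_start & t < t_end
      burst_sigma <- 20 * max(noise_sigma_ohm, 0.05)
      noise[in_ev] <- noise[in_ev] + stats::rnorm(sum(in_ev), 0, burst_sigma)
    }
    event_term <- event_term + add
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      kind = ev$kind, t_start = ev$t_start, t_end = t_end,
      duration_s = ev$duration_s, magnitude = ev$magnitude
    )
  }
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else {
    tibble::tibble(kind = character(0), t_start = numeric(0), t_end = numeric(0),
                   duration_s = numeric(0), magnitude = numeric(0))
  }

  z <- baseline_ohm + carrier + event_term + noise
  trace <- impedance_trace(t, z, rate_hz = rate_hz, meta = list(
    source = "simulated", seed = as.integer(seed),
    resp_rate_bpm = resp_rate_bpm, resp_amplitude_ohm = resp_amplitude_ohm
  ))
  structure(list(
    trace = trace,
    truth = truth,
    decomposition = tibble::tibble(
      time_s = t, baseline = baseline_ohm, carrier = carrier,
      event = event_term, noise = noise
    )
  ), class = "vae_simulation")
}

check_event_conflicts <- function(events) {
  overlap <- function(a, b) {
    a$t_start < b$t_start + b$duration_s && b$t_start < a$t_start + a$duration_s
  }
  carrier_kinds <- c("tv_step", "irregular_ventilation")
  for (a in events) {
    for (b in events) {
      if (a$kind == "apnea_interval" && b$kind %in% carrier_kinds && overlap(a, b)) {
        stop("configuration error: apnea_interval overlaps ", b$kind,
             " — there is no carrier to modify during apnoea", call. = FALSE)
      }
    }
  }
  invisible(events)
}

#' Write the standard seeded fixture suite
#'
#' Generates the named simulation scenarios the detector is exercised
#' against — clean ventilation at 6/12/20/30 bpm, a gradual entrainment
#' ramp, a bolus blip, tidal-volume and PEEP confounders, apnoea with
#' sustained baseline steps (circulation without ventilation), a
#' cautery-corrupted trace and irregular hand ventilation — as trace CSVs
#' with ground-truth JSON event logs. Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; each scenario derives its own from it.
#' @param duration_s Length of each scenario trace.
#' @return Invisibly, a tibble with `name`, `trace_path`, `truth_path`.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, duration_s = 90) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- fixture_scenarios(seed, duration_s)
  rows <- lapply(names(scen), function(nm) {
    sim <- do.call(simulate_trace, scen[[nm]])
    trace_path <- file.path(out_dir, paste0(nm, ".csv"))
    truth_path <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_trace(sim$trace, trace_path)
    jsonlite::write_json(
      list(name = nm, events = sim$truth),
      truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    tibble::tibble(name = nm, trace_path = trace_path, truth_path = truth_path)
  })
  invisible(dplyr::bind_rows(rows))
}

fixture_scenarios <- function(seed, duration_s) {
  s <- function(k) as.integer(seed) * 100L + k
  half <- duration_s / 2
  list(
    clean_06bpm = list(duration_s = duration_s, resp_rate_bpm = 6, seed = s(1L)),
    clean_12bpm = list(duration_s = duration_s, resp_rate_bpm = 12, seed = s(2L)),
    clean_20bpm = list(duration_s = duration_s, resp_rate_bpm = 20, seed = s(3L)),
    clean_30bpm = list(duration_s = duration_s, resp_rate_bpm = 30, seed = s(4L)),
    gradual_vae_ramp = list(
      duration_s = duration_s, resp_rate_bpm = 12, noise_sigma_ohm = 0.2,
      seed = s(5L),
      events = list(sim_event("ramp", t_start = half, duration_s = 30, magnitude = 1))
    ),
    bolus_blip = list(
      duration_s = duration_s, resp_rate_bpm = 12, seed = s(6L),
      events = list(sim_event("blip", t_start = half, duration_s = 1, magnitude = 14))
    ),
    tv_confounder = list(
      duration_s = duration_s, resp_rate_bpm = 12, resp_amplitude_ohm = 5,
      seed = s(7L),
      events = list(sim_event("tv_step", t_start = half, duration_s = duration_s - half,
                              magnitude = 9 / 5))
    ),
    peep_confounder = list(
      duration_s = duration_s, resp_rate_bpm = 12, seed = s(8L),
      events = list(sim_event("peep_step", t_start = half, duration_s = duration_s - half,
                              magnitude = 2))
    ),
    apnea_baseline_steps = list(
      duration_s = duration_s, resp_rate_bpm = 0, noise_sigma_ohm = 0.05,
      seed = s(9L),
      events = list(
        sim_event("baseline_step", t_start = duration_s / 3, duration_s = 1, magnitude = 2),
        sim_event("baseline_step", t_start = 2 * duration_s / 3, duration_s = 1, magnitude = 2)
      )
    ),
    cautery_corrupted = list(
      duration_s = duration_s, resp_rate_bpm = 12, seed = s(10L),
      events = list(
        sim_event("cautery_burst", t_start = duration_s / 3, duration_s = 4),
        sim_event("cautery_burst", t_start = 2 * duration_s / 3, duration_s = 4)
      )
    ),
    irregular_hand_ventilation = list(
      duration_s = duration_s, resp_rate_bpm = 12, seed = s(11L),
      events = list(sim_event("irregular_ventilation", t_start = 0,
                              duration_s = duration_s, magnitude = 0.25))
    )
  )
}
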