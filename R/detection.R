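#' Detect transient impedance blips
#'
#' A blip is a rapid, brief rise in impedance above the local baseline — the
#' signature of a large air bolus passing the sensed volume. The raw trace
#' is compared against a rolling-median baseline; maximal runs where the
#' residual exceeds a threshold are kept as blips when they last no longer
#' than `detection$max_blip_s` (longer excursions are left to the trend and
#' absolute-rise paths). The threshold is `detection$blip_k` times the local
#' respiratory excursion above the end-expiratory level (median of
#' `z_max - z_p25` across the window's cycles — the crest height of a
#' normal breath over the rolling median can approach the full excursion
#' when expiration ends in a pause) when valid ventilation is present, or
#' the absolute floor `detection$blip_floor_ohm` otherwise. Runs shorter
#' than `detection$min_blip_s` are discarded as threshold chatter. Onsets/offsets are refined to
#' the 10%-of-rise crossing so reported timing is insensitive to the
#' respiratory phase at which the bolus arrives.
#'
#' @param trace The unsmoothed [impedance_trace()].
#' @param cycles A `resp_cycles` object for the same span (may be invalid).
#' @param config A [vae_config()] list.
#' @return A tibble with one row per blip: `t_onset`, `t_offset`,
#'   `duration_s`, `amplitude_ohm`.
#' @export
detect_blips <- function(trace, cycles, config = vae_config()) {
  empty <- tibble::tibble(t_onset = numeric(0), t_offset = numeric(0),
                          duration_s = numeric(0), amplitude_ohm = numeric(0))
  n <- nrow(trace)
  if (n == 0L) return(empty)
  rate <- trace_rate(trace)
  z <- trace$impedance_ohm

  base_win_s <- if (cycles_valid(cycles)) {
    2 * stats::median(cycles$t_end - cycles$t_start)
  } else 5
  k <- as.integer(round(base_win_s * rate))
  k <- min(k, n - (1 - n %% 2L)) # runmed needs odd k <= n
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, k)
  if (k > n) return(empty)
  baseline <- stats::runmed(z, k, endrule = "med")
  resid <- z - baseline

  thr <- if (cycles_valid(cycles) && nrow(cycles) > 0) {
    config$detection$blip_k * stats::median(cycles$z_max - cycles$z_p25)
  } else {
    config$detection$blip_floor_ohm
  }

  above <- resid > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  max_walk <- as.integer(round(0.25 * rate))
  rows <- list()
  for (ri in runs) {
    a <- starts[ri]
    b <- ends[ri]
    m <- max(resid[a:b])
    # refine onset/offset to the 10%-of-rise crossing above the local
    # pre-event level, walking only while the edge stays monotone so the
    # walk stops at the respiratory waveform instead of riding it
    pre_idx <- max(1L, a - as.integer(round(0.5 * rate))):max(1L, a - 1L)
    pre <- stats::median(resid[pre_idx])
    lvl <- pre + 0.1 * (m - pre)
    i <- a
    while (i > 1L && i > a - max_walk && resid[i - 1L] > lvl && resid[i - 1L] < resid[i]) {
      i <- i - 1L
    }
    j <- b
    while (j < n && j < b + max_walk && resid[j + 1L] > lvl && resid[j + 1L] < resid[j]) {
      j <- j + 1L
    }
    # the true edge crossed the 10% level between samples i-1 and i, so
    # report the bracketing outer samples
    i <- max(1L, i - 1L)
    j <- min(n, j + 1L)
    dur <- (j - i) / rate
    if (dur >= config$detection$min_blip_s && dur <= config$detection$max_blip_s) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_onset = trace$time_s[i], t_offset = trace$time_s[j],
        duration_s = dur, amplitude_ohm = m
      )
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Compare consecutive respiratory cycles
#'
#' Computes the change in end-expiratory (EEI, 25th percentile) and
#' end-inspiratory (EII, 75th percentile) impedance between each cycle and
#' its predecessor, and classifies the pair against the trend threshold
#' `tau`:
#'
#' * `vae_or_peep` — both EEI and EII rose by more than `tau`: the paired
#'   rise expected from air entrainment (or from a PEEP increase — the
#'   ambiguity is surfaced, not resolved).
#' * `tv_change` — only EII changed by more than `tau` in magnitude: a
#'   tidal-volume change moves the end-inspiratory level alone.
#' * `peep_tv_edge` — only EEI rose by more than `tau`: the uncommon
#'   PEEP-up/TV-down combination.
#' * `stable` — neither threshold exceeded.
#'
#' @param cycles A `resp_cycles` object.
#' @param tau Trend threshold in ohms.
#' @return A tibble with one row per consecutive pair: `t` (end of the later
#'   cycle), `d_eei`, `d_eii`, `classification`. Empty when fewer than two
#'   cycles are available.
#' @export
compare_cycles <- function(cycles, tau = 0.1) {
  if (nrow(cycles) < 2L) {
    return(tibble::tibble(t = numeric(0), d_eei = numeric(0),
                          d_eii = numeric(0), classification = character(0)))
  }
  d_eei <- diff(cycles$z_p25)
  d_eii <- diff(cycles$z_p75)
  classification <- dplyr::case_when(
    d_eei > tau & d_eii > tau ~ "vae_or_peep",
    abs(d_eii) > tau & abs(d_eei) <= tau ~ "tv_change",
    d_eei > tau & abs(d_eii) <= tau ~ "peep_tv_edge",
    .default = "stable"
  )
  tibble::tibble(t = cycles$t_end[-1L], d_eei = d_eei, d_eii = d_eii,
                 classification = classification)
}

#' Absolute-rise detection for unventilated signals
#'
#' When no valid respiratory waveform is present (apnoea, or circulation
#' without ventilation), the cycle-based trend path has nothing to compare.
#' This path instead compares the median impedance of the most recent
#' `absolute_ref_s` seconds against a slowly adapting reference baseline: a
#' sustained rise of `absolute_rise_ohm` maps exactly to the alarm
#' threshold, larger rises score proportionally higher (capped at 100).
#' Because the comparison uses window medians, brief excursions (blips) do
#' not move it.
#'
#' @param trace The unsmoothed [impedance_trace()] for the current window.
#' @param cycles A `resp_cycles` object (used only to note validity).
#' @param config A [vae_config()] list.
#' @param reference Adapting reference baseline in ohms from previous
#'   windows; when `NULL`, the median of the first `absolute_ref_s` seconds
#'   of the window is used.
#' @return A list with `component` (0-100), `rise_ohm` and `reference`.
#' @export
detect_absolute_rise <- function(trace, cycles, config = vae_config(),
                                 reference = NULL) {
  if (nrow(trace) == 0L) {
    return(list(component = 0, rise_ohm = 0, reference = reference))
  }
  rate <- trace_rate(trace)
  span <- as.integer(round(config$detection$absolute_ref_s * rate))
  n <- nrow(trace)
  if (is.null(reference)) {
    reference <- stats::median(trace$impedance_ohm[seq_len(min(span, n))])
  }
  current <- stats::median(trace$impedance_ohm[max(1L, n - span + 1L):n])
  rise <- current - reference
  component <- min(100, config$detection$alarm_threshold *
                     max(0, rise) / config$detection$absolute_rise_ohm)
  list(component = component, rise_ohm = rise, reference = reference)
}

#' Combine detection evidence into a VAE assessment
#'
#' The window score is the maximum of three 0-100 components (the blip and
#' trend modalities are alternative evidence for the same physical event, so
#' taking the maximum avoids double counting):
#'
#' * trend — accumulates evidence of a sustained paired rise: the length of
#'   the consecutive `vae_or_peep` run (saturating at
#'   `trend_run_saturation` deltas) and a cumulative common-mode rise
#'   tracker that sums `min(d_eei, d_eii)` over successive cycles, floored
#'   at zero and saturating at `trend_rise_saturation_ohm`; the component is
#'   the larger of the two, so a single large paired step and a slow
#'   multi-cycle ramp both reach the alarm threshold. Non-`vae_or_peep` deltas hold the
#'   run (a pause in entrainment is not evidence against it) unless a
#'   paired fall beyond `tau` contradicts it, which resets the run. A level
#'   change landing mid-cycle splits across two adjacent comparisons — the
#'   straddling cycle's 75th percentile responds in the cycle containing
#'   the change and its 25th percentile one cycle later — so an isolated
#'   EII rise immediately followed by an isolated EEI rise (or vice versa)
#'   is fused into a single paired rise. The run state can be threaded
#'   across analysis windows (`trend_run`, `trend_rise_ohm`,
#'   `last_delta_t`, `pending_kind`, `pending_val`), which the
#'   sliding-window pipeline uses so that evidence spanning window
#'   boundaries is not lost; deltas up to `last_delta_t` (plus half a
#'   minimum breath period, to absorb boundary jitter in overlapping
#'   windows) are treated as already counted.
#' * blip — the largest blip amplitude relative to `blip_alarm_scale` times
#'   the respiratory range (or `blip_alarm_floor_ohm` when unventilated).
#' * absolute — the unventilated absolute-rise component, passed through
#'   when cycles are invalid.
#'
#' The alarm raises when the score reaches `alarm_threshold` and the signal
#' quality permits (`sqi >= sqi$floor`); the absolute path, designed for
#' exactly the situation where no respiratory signal exists and the SQI is
#' therefore poor, raises the alarm regardless of the SQI floor. When a
#' score crosses the threshold but quality vetoes it, the assessment is
#' flagged `suppressed_low_sqi`.
#'
#' @param deltas Cycle deltas from [compare_cycles()].
#' @param blips Blip events from [detect_blips()].
#' @param absolute Absolute-rise component (0-100).
#' @param sqi An `sqi_report` from [compute_sqi()].
#' @param cycles The `resp_cycles` the deltas came from.
#' @param config A [vae_config()] list.
#' @param trend_run,trend_rise,last_delta_t,pending_kind,pending_val
#'   Trend-run state carried from a previous window (defaults start a
#'   fresh run).
#' @return A one-row tibble: `score`, `trend_component`, `blip_component`,
#'   `absolute_component`, `alarm_raw`, `suppressed_low_sqi`, plus the
#'   updated run state `trend_run`, `trend_rise_ohm`, `last_delta_t`,
#'   `pending_kind` and `pending_val`.
#' @export
vae_score <- function(deltas, blips, absolute, sqi, cycles,
                      config = vae_config(),
                      trend_run = 0L, trend_rise = 0, last_delta_t = -Inf,
                      pending_kind = "", pending_val = 0) {
  det <- config$detection
  margin <- config$peaks$min_period_s / 2
  if (nrow(deltas) > 0L) {
    new <- deltas[deltas$t > last_delta_t + margin, , drop = FALSE]
    if (nrow(new) > 0L) {
      for (i in seq_len(nrow(new))) {
        d_eei <- new$d_eei[i]
        d_eii <- new$d_eii[i]
        d_min <- min(d_eei, d_eii)
        cls <- new$classification[i]
        if (cls == "vae_or_peep") {
          trend_run <- trend_run + 1L
          trend_rise <- max(0, trend_rise + d_min)
          pending_kind <- ""
        } else if (d_eei < -det$tau_ohm && d_eii < -det$tau_ohm) {
          # paired fall: positive contradiction of an entrainment trend
          trend_run <- 0L
          trend_rise <- 0
          pending_kind <- ""
        } else if (cls == "tv_change" && d_eii > det$tau_ohm) {
          # isolated EII rise. A level change landing mid-cycle splits into
          # an EII-only delta and an EEI-only delta on adjacent comparisons
          # (the straddling cycle's percentiles respond at different
          # phases), so a complementary isolated rise on the previous
          # delta completes a paired rise.
          if (pending_kind == "eei") {
            trend_run <- trend_run + 1L
            trend_rise <- max(0, trend_rise + min(pending_val, d_eii))
            pending_kind <- ""
          } else {
            pending_kind <- "eii"
            pending_val <- d_eii
            # the paired minimum still carries any common-mode component
            # (near zero for a genuine tidal-volume change)
            trend_rise <- max(0, trend_rise + d_min)
          }
        } else if (cls == "peep_tv_edge") {
          if (pending_kind == "eii") {
            trend_run <- trend_run + 1L
            trend_rise <- max(0, trend_rise + min(pending_val, d_eei))
            pending_kind <- ""
          } else {
            pending_kind <- "eei"
            pending_val <- d_eei
            trend_rise <- max(0, trend_rise + d_min)
          }
        } else {
          # equivocal cycle: not evidence against entrainment — keep the
          # run and let the common-mode rise tracker absorb the sub-tau
          # paired change (negative changes decay it, floored at zero)
          trend_rise <- max(0, trend_rise + d_min)
          pending_kind <- ""
        }
      }
      last_delta_t <- max(new$t)
    }
  }
  trend_component <- 100 * min(1, max(trend_run / det$trend_run_saturation,
                                      trend_rise / det$trend_rise_saturation_ohm))
  trend_component <- max(0, trend_component)

  blip_component <- 0
  if (nrow(blips) > 0L) {
    ref <- if (cycles_valid(cycles) && nrow(cycles) > 0L) {
      det$blip_alarm_scale * stats::median(cycles$z_max - cycles$z_p25)
    } else {
      det$blip_alarm_floor_ohm
    }
    blip_component <- 100 * min(1, max(blips$amplitude_ohm) / ref)
  }

  absolute_component <- if (cycles_valid(cycles)) 0 else min(100, max(0, absolute))
  score <- max(0, min(100, max(trend_component, blip_component, absolute_component)))
  sqi_ok <- sqi$value >= config$sqi$floor
  alarm_raw <- (score >= det$alarm_threshold && sqi_ok) ||
    absolute_component >= det$alarm_threshold
  suppressed <- score >= det$alarm_threshold && !sqi_ok &&
    absolute_component < det$alarm_threshold
  tibble::tibble(
    score = score,
    trend_component = trend_component,
    blip_component = blip_component,
    absolute_component = absolute_component,
    trend_run = trend_run,
    trend_rise_ohm = trend_rise,
    last_delta_t = last_delta_t,
    pending_kind = pending_kind,
    pending_val = pending_val,
    alarm_raw = alarm_raw,
    suppressed_low_sqi = suppressed
  )
}
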