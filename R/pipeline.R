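# Sliding-window orchestration shared by batch and streaming analysis. Both
# paths plan identical windows, assess each window with the same function and
# thread the same sequential state (absolute-rise reference baseline, alarm
# hysteresis), so stream output is bit-for-bit equal to batch output.

plan_full_windows <- function(buffered_s, config) {
  det <- config$detection
  step <- det$window_s * (1 - det$overlap)
  starts <- numeric(0)
  s <- 0
  while (s + det$window_s <= buffered_s + 1e-9) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

plan_tail_window <- function(duration_s, config) {
  det <- config$detection
  step <- det$window_s * (1 - det$overlap)
  full <- plan_full_windows(duration_s, config)
  s_next <- if (length(full)) full[length(full)] + step else 0
  if (s_next + det$window_s > duration_s + 1e-9 &&
      duration_s - s_next >= det$min_window_s - 1e-9) s_next else NULL
}

new_stream_state <- function(config) {
  list(config = config, abs_reference = NULL, alarm_on = FALSE, below = 0L,
       trend_run = 0L, trend_rise = 0, last_delta_t = -Inf,
       pending_kind = "", pending_val = 0)
}

assess_window <- function(wtrace, t_start, state) {
  config <- state$config
  det <- config$detection
  cycles <- respiratory_cycles(wtrace, config)
  sqi <- compute_sqi(wtrace, cycles, config)
  blips <- detect_blips(wtrace, cycles, config)
  deltas <- compare_cycles(cycles, det$tau_ohm)
  absr <- detect_absolute_rise(wtrace, cycles, config, reference = state$abs_reference)
  sc <- vae_score(deltas, blips, absr$component, sqi, cycles, config,
                  trend_run = state$trend_run, trend_rise = state$trend_rise,
                  last_delta_t = state$last_delta_t,
                  pending_kind = state$pending_kind,
                  pending_val = state$pending_val)
  state$trend_run <- sc$trend_run
  state$trend_rise <- sc$trend_rise_ohm
  state$last_delta_t <- sc$last_delta_t
  state$pending_kind <- sc$pending_kind
  state$pending_val <- sc$pending_val

  # slow adaptation of the apnoea reference while quiescent; frozen during a
  # candidate rise so the rise itself is not absorbed
  rate <- trace_rate(wtrace)
  span <- as.integer(round(det$absolute_ref_s * rate))
  n <- nrow(wtrace)
  cur_med <- stats::median(wtrace$impedance_ohm[max(1L, n - span + 1L):n])
  state$abs_reference <- if (absr$component < det$alarm_threshold / 2) {
    (1 - det$absolute_adapt) * absr$reference + det$absolute_adapt * cur_med
  } else {
    absr$reference
  }

  # alarm hysteresis: raise immediately, clear after `alarm_clear_windows`
  # consecutive quiet windows
  if (sc$alarm_raw) {
    state$alarm_on <- TRUE
    state$below <- 0L
  } else if (state$alarm_on) {
    state$below <- state$below + 1L
    if (state$below >= det$alarm_clear_windows) {
      state$alarm_on <- FALSE
      state$below <- 0L
    }
  }

  row <- tibble::tibble(
    t_start = t_start,
    t_window = t_start + trace_duration(wtrace),
    valid = cycles_valid(cycles),
    rate_bpm = cycles_rate(cycles),
    n_cycles = nrow(cycles),
    score = sc$score,
    trend_component = sc$trend_component,
    blip_component = sc$blip_component,
    absolute_component = sc$absolute_component,
    alarm = state$alarm_on,
    alarm_raw = sc$alarm_raw,
    suppressed_low_sqi = sc$suppressed_low_sqi,
    sqi = sqi$value,
    events = list(blips)
  )
  list(row = row, state = state)
}

finalize_analysis <- function(rows, config) {
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    t_start = numeric(0), t_window = numeric(0), valid = logical(0),
    rate_bpm = numeric(0), n_cycles = integer(0), score = numeric(0),
    trend_component = numeric(0), blip_component = numeric(0),
    absolute_component = numeric(0), alarm = logical(0), alarm_raw = logical(0),
    suppressed_low_sqi = logical(0), sqi = numeric(0), events = list()
  )
  attr(out, "config") <- config
  class(out) <- c("vae_analysis", class(tibble::tibble()))
  out
}

#' Analyse a trace for venous air embolism evidence
#'
#' Runs the full detection pipeline over a sliding analysis window (default
#' 30 s with 50% overlap): smoothing, wavelet peak detection, rate
#' validation, cycle segmentation, SQI, blip detection, paired EEI/EII trend
#' comparison, the unventilated absolute-rise path and score/alarm logic.
#' Windows shorter than `detection$min_window_s` are withheld as warm-up; a
#' trailing partial window is analysed when long enough. Analysis of a fixed
#' trace is fully deterministic, and [stream_trace()] on chunks of the same
#' trace produces an identical assessment sequence.
#'
#' @param trace An [impedance_trace()].
#' @param config A [vae_config()] list.
#' @return A tibble of class `vae_analysis`, one row per analysis window:
#'   window bounds, ventilation validity and rate, the 0-100 `score` with
#'   its trend/blip/absolute components, `alarm` (with hysteresis),
#'   `suppressed_low_sqi`, `sqi`, and a list-column `events` of detected
#'   blips.
#' @examples
#' sim <- simulate_trace(duration_s = 60, seed = 42)
#' analyze_trace(sim$trace)
#' @export
analyze_trace <- function(trace, config = vae_config()) {
  dur <- trace_duration(trace)
  state <- new_stream_state(config)
  rows <- list()
  for (s in plan_full_windows(dur, config)) {
    w <- trace_window(trace, s, s + config$detection$window_s)
    res <- assess_window(w, if (nrow(trace)) trace$time_s[1] + s else s, state)
    state <- res$state
    rows[[length(rows) + 1L]] <- res$row
  }
  tail_s <- plan_tail_window(dur, config)
  if (!is.null(tail_s)) {
    w <- trace_window(trace, tail_s, dur)
    res <- assess_window(w, if (nrow(trace)) trace$time_s[1] + tail_s else tail_s, state)
    rows[[length(rows) + 1L]] <- res$row
  }
  finalize_analysis(rows, config)
}

#' Streaming analysis over arriving chunks
#'
#' Consumes an ordered list of trace chunks (e.g. from [replay()]) as if
#' they arrived live, emitting each analysis window as soon as the buffered
#' signal covers it and handling the trailing partial window when the stream
#' ends. The emitted sequence is identical to [analyze_trace()] on the
#' concatenated trace.
#'
#' @param chunks List of [impedance_trace()] chunks in time order.
#' @param config A [vae_config()] list.
#' @param on_window Optional callback invoked with each assessment row as it
#'   is emitted (for live printing).
#' @return A `vae_analysis` tibble (see [analyze_trace()]).
#' @export
stream_trace <- function(chunks, config = vae_config(), on_window = NULL) {
  state <- new_stream_state(config)
  rows <- list()
  buf_t <- numeric(0)
  buf_z <- numeric(0)
  rate <- NULL
  meta <- list()
  emitted <- 0L
  for (ch in chunks) {
    if (nrow(ch) == 0L) next
    if (is.null(rate)) {
      rate <- trace_rate(ch)
      meta <- trace_meta(ch)
    }
    buf_t <- c(buf_t, ch$time_s)
    buf_z <- c(buf_z, ch$impedance_ohm)
    buffered_s <- length(buf_t) / rate
    starts <- plan_full_windows(buffered_s, config)
    while (emitted < length(starts)) {
      s <- starts[emitted + 1L]
      buf <- new_impedance_trace(
        tibble::tibble(time_s = buf_t, impedance_ohm = buf_z),
        rate_hz = rate, meta = meta
      )
      w <- trace_window(buf, s, s + config$detection$window_s)
      res <- assess_window(w, buf_t[1] + s, state)
      state <- res$state
      rows[[length(rows) + 1L]] <- res$row
      if (!is.null(on_window)) on_window(res$row)
      emitted <- emitted + 1L
    }
  }
  if (!is.null(rate)) {
    dur <- length(buf_t) / rate
    tail_s <- plan_tail_window(dur, config)
    if (!is.null(tail_s)) {
      buf <- new_impedance_trace(
        tibble::tibble(time_s = buf_t, impedance_ohm = buf_z),
        rate_hz = rate, meta = meta
      )
      w <- trace_window(buf, tail_s, dur)
      res <- assess_window(w, buf_t[1] + tail_s, state)
      rows[[length(rows) + 1L]] <- res$row
      if (!is.null(on_window)) on_window(res$row)
    }
  }
  finalize_analysis(rows, config)
}
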