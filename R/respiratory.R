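#' Causal running-average smoothing
#'
#' Applies a time-delayed (trailing) running average: the output at time `t`
#' is the mean of the input samples in `(t - window_s, t]`. The window is
#' causal, so reported values lag the underlying signal by about half the
#' window; the first `window_s` seconds use the partially filled window and
#' are recorded as warm-up in the trace metadata. The default 0.5 s window
#' suppresses sample-level noise without blunting the breath waveform (or
#' the brief bolus "blips", which the detector reads from the raw trace).
#'
#' @param trace An [impedance_trace()]; must be non-empty and longer than
#'   the smoothing window.
#' @param window_s Window length in seconds.
#' @return A smoothed `impedance_trace` at the same sample rate, with
#'   `meta$warmup_s` set.
#' @export
smooth_trace <- function(trace, window_s = 0.5) {
  if (nrow(trace) == 0L) stop("trace is empty", call. = FALSE)
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0) {
    stop("invalid configuration: `window_s` must be positive", call. = FALSE)
  }
  if (window_s >= trace_duration(trace)) {
    stop("invalid configuration: smoothing window longer than trace", call. = FALSE)
  }
  w <- max(1L, as.integer(round(window_s * trace_rate(trace))))
  z <- trace$impedance_ohm
  cs <- cumsum(z)
  n <- length(z)
  out <- numeric(n)
  head_n <- seq_len(min(w, n))
  out[head_n] <- cs[head_n] / head_n # expanding mean during warm-up
  if (n > w) {
    idx <- (w + 1L):n
    out[idx] <- (cs[idx] - cs[idx - w]) / w
  }
  meta <- trace_meta(trace)
  meta$warmup_s <- window_s
  new_impedance_trace(
    tibble::tibble(time_s = trace$time_s, impedance_ohm = out),
    rate_hz = trace_rate(trace), meta = meta
  )
}

#' Detect respiratory peaks by wavelet ridge detection
#'
#' Finds end-inspiratory peaks of the (smoothed) impedance waveform with a
#' continuous wavelet transform: Ricker wavelets at `n_scales`
#' logarithmically spaced scales covering breath periods from `min_period_s`
#' to `max_period_s`, per-scale maxima linked into ridge lines, and ridges
#' that persist across scales reported as peaks. Detected peaks are snapped
#' to the local maximum of the trace and peaks closer than `min_period_s`
#' are merged keeping the higher one (ties broken toward the earlier peak).
#'
#' @param trace A smoothed [impedance_trace()] of at least `max_period_s`
#'   duration.
#' @param min_period_s,max_period_s Plausible breath period band in seconds
#'   (defaults 2 and 10 s, i.e. 6-30 breaths per minute).
#' @param n_scales Number of wavelet scales.
#' @return Numeric vector of peak times in seconds (possibly empty).
#' @export
detect_peaks <- function(trace, min_period_s = 2, max_period_s = 10, n_scales = 16) {
  if (trace_duration(trace) < max_period_s) {
    stop("trace shorter than one maximum respiratory period", call. = FALSE)
  }
  rate <- trace_rate(trace)
  z <- trace$impedance_ohm
  x <- z - stats::median(z)
  # Ricker best responds to an oscillation of period T at scale ~ T/4
  scales <- exp(seq(log(min_period_s * rate / 4), log(max_period_s * rate / 4),
                    length.out = n_scales))
  mat <- cwt_ricker(x, scales)
  cols <- cwt_peaks(mat, scales)
  if (!length(cols)) return(numeric(0))
  # snap to the local waveform maximum near each ridge position
  snap <- as.integer(round(min_period_s * rate / 4))
  n <- length(z)
  cols <- vapply(cols, function(i) {
    lo <- max(1L, as.integer(i) - snap)
    hi <- min(n, as.integer(i) + snap)
    lo + which.max(z[lo:hi]) - 1L
  }, integer(1))
  cols <- sort(unique(cols))
  # Merge peaks closer than the minimum period, keeping the higher value.
  # Merging is for sporadic double detections only: when short gaps are
  # systematic the oscillation itself is faster than the band, and merging
  # would alias it into the band — leave the train intact so rate
  # validation can reject it.
  min_gap <- min_period_s * rate
  if (length(cols) >= 2L && mean(diff(cols) < min_gap) <= 0.3) {
    repeat {
      if (length(cols) < 2L) break
      gaps <- diff(cols)
      j <- which(gaps < min_gap)
      if (!length(gaps) || !length(j)) break
      j <- j[1]
      drop <- if (z[cols[j + 1]] > z[cols[j]]) j else j + 1L
      cols <- cols[-drop]
    }
  }
  # prominence filter: drop peaks standing far lower above their adjacent
  # troughs than the typical peak does — noise bumps between true breaths
  # (long expiratory pauses) otherwise fabricate an in-band rate
  if (length(cols) >= 3L) {
    prom <- vapply(seq_along(cols), function(k) {
      lo <- if (k == 1L) 1L else cols[k - 1L]
      hi <- if (k == length(cols)) n else cols[k + 1L]
      z[cols[k]] - max(min(z[lo:cols[k]]), min(z[cols[k]:hi]))
    }, numeric(1))
    cols <- cols[prom >= 0.25 * stats::median(prom)]
  }
  trace$time_s[cols]
}

#' Validate a peak train against the plausible ventilation band
#'
#' A peak train is accepted as a respiratory signal when it has at least
#' three peaks, the median inter-peak interval lies within the surgical
#' ventilation band (6-30 breaths per minute, i.e. periods of 2-10 s, with
#' a 3% allowance at each edge so that detection jitter cannot disqualify a
#' train whose true rate sits exactly on a band boundary), and the
#' intervals are regular: median absolute deviation of the intervals no
#' more than `regularity_mad_frac` of the median interval.
#'
#' @param peaks Numeric vector of peak times in seconds.
#' @param min_period_s,max_period_s Accepted period band in seconds.
#' @param regularity_mad_frac Regularity gate as a fraction of the median
#'   interval.
#' @return A list with `valid` (logical), `rate_bpm` (breaths per minute,
#'   `NA` when invalid), and `intervals` (the inter-peak intervals).
#' @export
validate_rate <- function(peaks, min_period_s = 2, max_period_s = 10,
                          regularity_mad_frac = 0.25) {
  iv <- diff(sort(peaks))
  if (length(peaks) < 3L) {
    return(list(valid = FALSE, rate_bpm = NA_real_, intervals = iv))
  }
  med <- stats::median(iv)
  mad1 <- stats::median(abs(iv - med))
  in_band <- med >= min_period_s * 0.97 && med <= max_period_s * 1.03
  regular <- mad1 <= regularity_mad_frac * med
  if (in_band && regular) {
    list(valid = TRUE, rate_bpm = 60 / med, intervals = iv)
  } else {
    list(valid = FALSE, rate_bpm = NA_real_, intervals = iv)
  }
}

#' Segment a trace into respiratory cycles with robust summaries
#'
#' Cycle boundaries are placed at the impedance minima (troughs) between
#' consecutive validated peaks, so every cycle contains exactly one
#' end-inspiratory peak. Within each cycle the minimum, maximum and the
#' 25th / 75th percentile values (linear interpolation between order
#' statistics) are computed; the 25th percentile serves as a robust
#' end-expiratory impedance (EEI) estimate and the 75th percentile as the
#' end-inspiratory impedance (EII) estimate, since inspiration raises chest
#' impedance and the percentiles resist brief noise artifacts that corrupt
#' raw extrema.
#'
#' @param trace The smoothed [impedance_trace()] the peaks were detected on.
#' @param peaks Peak times from [detect_peaks()].
#' @param validation Optional result of [validate_rate()] for `peaks`;
#'   computed if omitted.
#' @param min_period_s,max_period_s,regularity_mad_frac Passed to
#'   [validate_rate()] when `validation` is not supplied.
#' @return A tibble of class `resp_cycles` with one row per cycle
#'   (`t_start`, `t_end`, `t_peak`, `z_min`, `z_max`, `z_p25`, `z_p75`,
#'   `n_samples`) and attributes `rate_bpm`, `valid` and `peaks`.
#' @export
segment_cycles <- function(trace, peaks, validation = NULL,
                           min_period_s = 2, max_period_s = 10,
                           regularity_mad_frac = 0.25) {
  if (is.null(validation)) {
    validation <- validate_rate(peaks, min_period_s, max_period_s, regularity_mad_frac)
  }
  empty <- tibble::tibble(
    t_start = numeric(0), t_end = numeric(0), t_peak = numeric(0),
    z_min = numeric(0), z_max = numeric(0), z_p25 = numeric(0),
    z_p75 = numeric(0), n_samples = integer(0)
  )
  if (!validation$valid || length(peaks) < 3L) {
    return(new_resp_cycles(empty, rate_bpm = validation$rate_bpm,
                           valid = FALSE, peaks = peaks))
  }
  peaks <- sort(peaks)
  t <- trace$time_s
  z <- trace$impedance_ohm
  pk_idx <- vapply(peaks, function(p) which.min(abs(t - p)), integer(1))
  troughs <- integer(length(peaks) - 1L)
  for (i in seq_len(length(peaks) - 1L)) {
    seg <- pk_idx[i]:pk_idx[i + 1L]
    # first sample reaching the segment minimum (within 2% of the local
    # range): when expiration ends in a flat pause the literal argmin
    # wanders over the pause with the noise, which would jitter the cycle
    # composition and hence the percentile summaries between repeats
    zmin <- min(z[seg])
    eps <- 0.02 * (max(z[seg]) - zmin)
    troughs[i] <- seg[which(z[seg] <= zmin + eps)[1]]
  }
  n_cyc <- length(troughs) - 1L
  rows <- lapply(seq_len(n_cyc), function(i) {
    # half-open [trough_i, trough_{i+1}) so cycles tile without overlap and
    # a stationary signal gives identical summaries in every cycle
    a <- troughs[i]
    b <- troughs[i + 1L]
    idx <- a:(b - 1L)
    zz <- z[idx]
    q <- stats::quantile(zz, c(0.25, 0.75), names = FALSE, type = 7)
    tibble::tibble(
      t_start = t[a], t_end = t[b], t_peak = t[pk_idx[i + 1L]],
      z_min = min(zz), z_max = max(zz), z_p25 = q[1], z_p75 = q[2],
      n_samples = length(idx)
    )
  })
  new_resp_cycles(dplyr::bind_rows(rows), rate_bpm = validation$rate_bpm,
                  valid = TRUE, peaks = peaks)
}

new_resp_cycles <- function(df, rate_bpm, valid, peaks) {
  out <- tibble::as_tibble(df)
  attr(out, "rate_bpm") <- rate_bpm
  attr(out, "valid") <- valid
  attr(out, "peaks") <- peaks
  class(out) <- c("resp_cycles", class(tibble::tibble()))
  out
}

#' @rdname segment_cycles
#' @param cycles A `resp_cycles` object.
#' @export
cycles_valid <- function(cycles) isTRUE(attr(cycles, "valid"))

#' @rdname segment_cycles
#' @export
cycles_rate <- function(cycles) attr(cycles, "rate_bpm")

#' Run the full respiratory segmentation pipeline
#'
#' Convenience wrapper: smooth, detect peaks, validate the rate and segment
#' into cycles with one call, using a configuration from [vae_config()].
#' Beyond the interval checks of [validate_rate()], the result is accepted
#' only if the respiratory excursion is physically plausible: the median
#' cycle range must reach `rate$min_range_ohm` and stand `rate$snr_gate`
#' noise sigmas above the high-frequency noise floor. Band-pass filtering
#' makes even white noise look quasi-periodic at breath-period scales, so
#' an interval test alone cannot reject a signal with no respiration in it.
#'
#' @param trace An [impedance_trace()].
#' @param config A [vae_config()] list.
#' @return A `resp_cycles` tibble (see [segment_cycles()]).
#' @export
respiratory_cycles <- function(trace, config = vae_config()) {
  sm <- smooth_trace(trace, config$smoothing$window_s)
  pk <- detect_peaks(sm, config$peaks$min_period_s, config$peaks$max_period_s,
                     config$peaks$n_scales)
  val <- validate_rate(pk, config$peaks$min_period_s, config$peaks$max_period_s,
                       config$rate$regularity_mad_frac)
  cyc <- segment_cycles(sm, pk, val)
  if (cycles_valid(cyc) && nrow(cyc) > 0L) {
    med_rng <- stats::median(cyc$z_max - cyc$z_min)
    sigma <- noise_floor_sigma(trace$impedance_ohm)
    if (med_rng < max(config$rate$min_range_ohm, config$rate$snr_gate * sigma)) {
      cyc <- new_resp_cycles(cyc[0, ], rate_bpm = NA_real_, valid = FALSE, peaks = pk)
    }
  }
  cyc
}
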