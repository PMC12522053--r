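#' Signal quality index
#'
#' Heuristic [0, 1] summary of whether the impedance signal is trustworthy
#' enough to alarm on, built from the presence, regularity and amplitude of
#' the respiratory waveform plus two consistency measures of the per-cycle
#' summaries. The value is a weighted mean of five named components:
#'
#' * `c_presence` — 1 when a plausible ventilation signal was validated,
#'   else 0.
#' * `c_regularity` — inter-peak interval consistency,
#'   `1 - min(1, MAD / (frac * median))` with the configured regularity
#'   fraction.
#' * `c_amplitude` — respiratory excursion versus the high-frequency noise
#'   floor (estimated from the median absolute successive difference of the
#'   unsmoothed trace), saturating at 1 for clean signals.
#' * `c_robustness` — agreement of the percentile summaries with the raw
#'   extrema: the mean fractional gap `((p25 - min) + (max - p75)) / range`
#'   compared with the value an ideal sinusoidal cycle would give
#'   (`1 - sqrt(2)/2`), penalising only excess gap (i.e. extrema inflated by
#'   spikes relative to the robust percentiles).
#' * `c_consistency` — stability of the per-cycle EEI/EII estimates across
#'   the window (normalised MAD of the 25th and 75th percentile series).
#'
#' @param trace The unsmoothed [impedance_trace()] for the analysis window.
#' @param cycles A `resp_cycles` object from [segment_cycles()] /
#'   [respiratory_cycles()] for the same window.
#' @param config A [vae_config()] list (weights, regularity fraction,
#'   amplitude SNR scale, consistency scale).
#' @return A one-row tibble of class `sqi_report`: `value`, `c_presence`,
#'   `c_regularity`, `c_amplitude`, `c_robustness`, `c_consistency`.
#' @export
compute_sqi <- function(trace, cycles, config = vae_config()) {
  if (nrow(trace) == 0L) stop("trace is empty", call. = FALSE)
  w <- config$sqi$weights
  valid <- cycles_valid(cycles)
  peaks <- attr(cycles, "peaks")
  if (is.null(peaks)) peaks <- numeric(0)

  c_presence <- as.numeric(valid)

  iv <- diff(sort(peaks))
  c_regularity <- if (length(iv) >= 2L) {
    med <- stats::median(iv)
    mad1 <- stats::median(abs(iv - med))
    if (med <= 0) 0 else 1 - min(1, mad1 / (config$rate$regularity_mad_frac * med))
  } else 0

  sigma <- noise_floor_sigma(trace$impedance_ohm)
  if (nrow(cycles) >= 1L) {
    rng <- cycles$z_max - cycles$z_min
    med_rng <- stats::median(rng)
    c_amplitude <- if (med_rng <= 0) 0 else {
      med_rng / (med_rng + config$sqi$amplitude_snr * sigma)
    }
    ok <- rng > 0
    c_robustness <- if (!any(ok)) 0 else {
      g <- mean(((cycles$z_p25 - cycles$z_min) + (cycles$z_max - cycles$z_p75))[ok] / rng[ok])
      g0 <- 1 - sqrt(2) / 2 # fractional gap of an ideal sampled sinusoid
      1 - min(1, max(0, g - g0) / (1 - g0))
    }
  } else {
    c_amplitude <- 0
    c_robustness <- 0
  }

  c_consistency <- if (nrow(cycles) >= 2L) {
    med_rng <- stats::median(cycles$z_max - cycles$z_min)
    if (med_rng <= 0) 0 else {
      d25 <- stats::median(abs(cycles$z_p25 - stats::median(cycles$z_p25)))
      d75 <- stats::median(abs(cycles$z_p75 - stats::median(cycles$z_p75)))
      disp <- (d25 + d75) / (2 * med_rng)
      1 - min(1, disp / config$sqi$consistency_scale)
    }
  } else 0

  comps <- c(presence = c_presence, regularity = c_regularity,
             amplitude = c_amplitude, robustness = c_robustness,
             consistency = c_consistency)
  value <- sum(unlist(w)[names(comps)] * comps)
  out <- tibble::tibble(
    value = value,
    c_presence = c_presence, c_regularity = c_regularity,
    c_amplitude = c_amplitude, c_robustness = c_robustness,
    c_consistency = c_consistency
  )
  class(out) <- c("sqi_report", class(out))
  out
}

# robust white-noise sigma from successive differences: for Gaussian noise
# diff(z) ~ N(0, 2 sigma^2), so sigma = median|diff| / (0.6745 * sqrt(2))
noise_floor_sigma <- function(z) {
  if (length(z) < 3L) return(0)
  stats::median(abs(diff(z))) / (0.6744898 * sqrt(2))
}
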