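#' Analysis configuration
#'
#' Builds the nested configuration list used throughout the pipeline,
#' merging overrides into the defaults and validating the result. Unknown
#' keys are rejected by name, all thresholds must be positive, and the SQI
#' component weights must sum to 1.
#'
#' Key groups (defaults in parentheses):
#' * `smoothing$window_s` (0.5 s) — trailing running-average window.
#' * `peaks$min_period_s` / `max_period_s` (2 / 10 s) — plausible breath
#'   period band (6-30 breaths per minute); `n_scales` (16) wavelet scales.
#' * `rate$regularity_mad_frac` (0.25) — inter-peak regularity gate;
#'   `min_range_ohm` (1) and `snr_gate` (4) — minimum respiratory excursion,
#'   absolute and in noise sigmas, for a peak train to count as ventilation.
#' * `detection$tau_ohm` (0.1 ohm) — between-cycle trend threshold, within
#'   the 0.01-1 ohm scale of clinically significant entrainment;
#'   `max_blip_s` (3 s) and `min_blip_s` (0.15 s) — duration bounds for a
#'   transient bolus blip;
#'   `blip_k` (1.5) — blip threshold in units of the local respiratory
#'   excursion above the end-expiratory level; `blip_floor_ohm` (1) — absolute blip threshold when no
#'   valid ventilation is present; `alarm_threshold` (50) — score at or
#'   above which the alarm raises; `absolute_rise_ohm` (1) — sustained
#'   unventilated rise that maps to the alarm threshold;
#'   `absolute_ref_s` (10 s) — reference/measurement span for the absolute
#'   path; `absolute_adapt` (0.1) — per-window EMA factor for the adapting
#'   reference baseline; `window_s` (30 s) and `overlap` (0.5) — sliding
#'   analysis window; `min_window_s` (10 s) — shortest analysable window;
#'   `trend_run_saturation` (8 deltas) and `trend_rise_saturation_ohm`
#'   (0.7 ohm) — trend-component saturation: the alarm threshold of 50
#'   corresponds to a confirmed cumulative paired rise of 0.35 ohm (well
#'   inside the 0.01-1 ohm clinically significant range, and more than
#'   threefold the per-cycle trend threshold) or 4 consecutive paired-rise
#'   cycles, chosen so that cycle segmentation's inherent lag of roughly one
#'   breath behind the window edge still leaves a slow entrainment ramp
#'   detectable within a handful of breaths; `blip_alarm_scale` (2) — blip
#'   amplitude, in respiratory ranges, that saturates the blip component;
#'   `blip_alarm_floor_ohm` (2 ohm) — the same reference when unventilated;
#'   `alarm_clear_windows` (2) — hysteresis before a raised alarm clears.
#' * `sqi$weights` (presence 0.35, regularity 0.2, amplitude 0.2,
#'   robustness 0.1, consistency 0.15); `floor` (0.3) — alarm-suppression
#'   threshold; `amplitude_snr` (5) — noise-floor multiplier in the
#'   amplitude component; `consistency_scale` (0.25) — dispersion scale of
#'   the consistency component.
#'
#' @param ... Named overrides, nested as in the defaults, e.g.
#'   `vae_config(detection = list(tau_ohm = 0.2))`.
#' @return A validated configuration list of class `vae_config`.
#' @export
vae_config <- function(...) {
  defaults <- list(
    smoothing = list(window_s = 0.5),
    peaks = list(min_period_s = 2, max_period_s = 10, n_scales = 16),
    rate = list(regularity_mad_frac = 0.25, min_range_ohm = 1, snr_gate = 4),
    detection = list(
      tau_ohm = 0.1,
      max_blip_s = 3,
      min_blip_s = 0.15,
      blip_k = 1.5,
      blip_floor_ohm = 1,
      alarm_threshold = 50,
      absolute_rise_ohm = 1,
      absolute_ref_s = 10,
      absolute_adapt = 0.1,
      window_s = 30,
      overlap = 0.5,
      min_window_s = 10,
      trend_run_saturation = 8,
      trend_rise_saturation_ohm = 0.7,
      blip_alarm_scale = 2,
      blip_alarm_floor_ohm = 2,
      alarm_clear_windows = 2
    ),
    sqi = list(
      weights = list(presence = 0.35, regularity = 0.2, amplitude = 0.2,
                     robustness = 0.1, consistency = 0.15),
      floor = 0.3,
      amplitude_snr = 5,
      consistency_scale = 0.25
    ),
    simulate = list(
      rate_hz = 100, baseline_ohm = 250, resp_rate_bpm = 12,
      resp_amplitude_ohm = 7, resp_shape = "skewed", noise_sigma_ohm = 0.1
    )
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = character(0))
  validate_vae_config(cfg)
  class(cfg) <- "vae_config"
  cfg
}

merge_config <- function(base, override, path) {
  if (length(override) == 0L) return(base)
  nm <- names(override)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  for (k in nm) {
    here <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[k]])) {
      if (!is.list(override[[k]])) {
        stop("configuration key ", here, " must be a list", call. = FALSE)
      }
      base[[k]] <- merge_config(base[[k]], override[[k]], c(path, k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

validate_vae_config <- function(cfg) {
  pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("configuration key ", nm, " must be a positive number", call. = FALSE)
    }
  }
  pos(cfg$smoothing$window_s, "smoothing.window_s")
  pos(cfg$peaks$min_period_s, "peaks.min_period_s")
  pos(cfg$peaks$max_period_s, "peaks.max_period_s")
  if (cfg$peaks$max_period_s <= cfg$peaks$min_period_s) {
    stop("peaks.max_period_s must exceed peaks.min_period_s", call. = FALSE)
  }
  pos(cfg$peaks$n_scales, "peaks.n_scales")
  pos(cfg$rate$regularity_mad_frac, "rate.regularity_mad_frac")
  pos(cfg$rate$min_range_ohm, "rate.min_range_ohm")
  pos(cfg$rate$snr_gate, "rate.snr_gate")
  for (k in c("tau_ohm", "max_blip_s", "min_blip_s", "blip_k", "blip_floor_ohm",
              "alarm_threshold", "absolute_rise_ohm", "absolute_ref_s",
              "window_s", "min_window_s", "trend_run_saturation",
              "trend_rise_saturation_ohm", "blip_alarm_scale",
              "blip_alarm_floor_ohm", "alarm_clear_windows")) {
    pos(cfg$detection[[k]], paste0("detection.", k))
  }
  if (cfg$detection$overlap < 0 || cfg$detection$overlap >= 1) {
    stop("detection.overlap must be in [0, 1)", call. = FALSE)
  }
  if (cfg$detection$absolute_adapt < 0 || cfg$detection$absolute_adapt > 1) {
    stop("detection.absolute_adapt must be in [0, 1]", call. = FALSE)
  }
  w <- unlist(cfg$sqi$weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("sqi.weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (cfg$sqi$floor < 0 || cfg$sqi$floor > 1) {
    stop("sqi.floor must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' Reads nested overrides from YAML and merges them into the defaults via
#' [vae_config()]; unknown keys are rejected with the offending key named.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A `vae_config` list.
#' @export
read_vae_config <- function(path = NULL) {
  if (is.null(path)) return(vae_config())
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(vae_config())
  do.call(vae_config, raw)
}
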