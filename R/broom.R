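#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a windowed analysis
#'
#' @param x A `vae_analysis` from [analyze_trace()] or [stream_trace()].
#' @param ... Unused.
#' @return A plain tibble, one row per window, with the blip list-column
#'   replaced by an `n_blips` count.
#' @method tidy vae_analysis
#' @export
tidy.vae_analysis <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_blips <- vapply(out$events, nrow, integer(1))
  out$events <- NULL
  out
}

#' @rdname tidy.vae_analysis
#' @method glance vae_analysis
#' @export
glance.vae_analysis <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_alarm_windows = sum(x$alarm),
    first_alarm_s = if (any(x$alarm)) min(x$t_window[x$alarm]) else NA_real_,
    max_score = if (nrow(x)) max(x$score) else NA_real_,
    median_sqi = if (nrow(x)) stats::median(x$sqi) else NA_real_,
    n_blips = sum(vapply(x$events, nrow, integer(1))),
    any_suppressed = any(x$suppressed_low_sqi)
  )
}

#' @rdname tidy.vae_analysis
#' @method glance resp_cycles
#' @export
glance.resp_cycles <- function(x, ...) {
  tibble::tibble(
    n_cycles = nrow(x),
    rate_bpm = cycles_rate(x),
    valid = cycles_valid(x),
    median_range_ohm = if (nrow(x)) stats::median(x$z_max - x$z_min) else NA_real_
  )
}

#' Plot an impedance trace
#'
#' @param object An [impedance_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot impedance_trace
#' @export
autoplot.impedance_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$impedance_ohm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Impedance (Ω)") +
    ggplot2::theme_minimal()
}

#' Plot a windowed VAE analysis
#'
#' Score per analysis window with the alarm threshold, alarm windows
#' highlighted, and the signal quality index alongside.
#'
#' @param object A `vae_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vae_analysis
#' @export
autoplot.vae_analysis <- function(object, ...) {
  cfg <- attr(object, "config")
  thr <- if (!is.null(cfg)) cfg$detection$alarm_threshold else 50
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_window)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$score), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$score, colour = .data$alarm)) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$sqi), colour = "darkgreen",
                       linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red")) +
    ggplot2::labs(x = "Window end (s)", y = "VAE score (SQI dotted, x100)",
                  colour = "Alarm") +
    ggplot2::theme_minimal()
}

#' Plot segmented respiratory cycles over a trace
#'
#' Overlays each cycle's min/max and robust 25th/75th percentile (EEI/EII)
#' summaries on the impedance waveform, in the style of a monitoring display.
#'
#' @param trace The (smoothed) [impedance_trace()] that was segmented.
#' @param cycles A `resp_cycles` object.
#' @return A ggplot.
#' @export
plot_cycles <- function(trace, cycles) {
  p <- autoplot(trace)
  if (nrow(cycles) == 0L) return(p)
  seg <- tidyr_longer_cycles(cycles)
  p +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_start, xend = .data$t_end, y = .data$level,
                   yend = .data$level, colour = .data$summary),
      inherit.aes = FALSE, linewidth = 0.6
    ) +
    ggplot2::labs(colour = "Cycle summary")
}

tidyr_longer_cycles <- function(cycles) {
  df <- tibble::as_tibble(cycles)[, c("t_start", "t_end", "z_min", "z_p25", "z_p75", "z_max")]
  out <- lapply(c(z_min = "z_min", `EEI (p25)` = "z_p25",
                  `EII (p75)` = "z_p75", z_max = "z_max"), function(col) {
    tibble::tibble(t_start = df$t_start, t_end = df$t_end, level = df[[col]])
  })
  dplyr::bind_rows(out, .id = "summary")
}
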