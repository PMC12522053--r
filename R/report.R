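#' Serialise an analysis to a report JSON
#'
#' Produces the per-window report record list and writes it as JSON with a
#' fixed key order and floats rounded to 6 significant digits, so repeated
#' runs on the same input are byte-identical.
#'
#' @param analysis A `vae_analysis` tibble.
#' @return `analysis_report()` returns the report as a list;
#'   `write_report()` writes it and returns `path` invisibly.
#' @export
analysis_report <- function(analysis) {
  windows <- lapply(seq_len(nrow(analysis)), function(i) {
    ev <- analysis$events[[i]]
    list(
      t_window = sig6(analysis$t_window[i]),
      score = sig6(analysis$score[i]),
      components = list(
        trend = sig6(analysis$trend_component[i]),
        blip = sig6(analysis$blip_component[i]),
        absolute = sig6(analysis$absolute_component[i])
      ),
      alarm = analysis$alarm[i],
      suppressed_low_sqi = analysis$suppressed_low_sqi[i],
      sqi = sig6(analysis$sqi[i]),
      valid_ventilation = analysis$valid[i],
      rate_bpm = if (is.na(analysis$rate_bpm[i])) NULL else sig6(analysis$rate_bpm[i]),
      events = lapply(seq_len(nrow(ev)), function(j) {
        list(
          t_onset = sig6(ev$t_onset[j]),
          t_offset = sig6(ev$t_offset[j]),
          duration_s = sig6(ev$duration_s[j]),
          amplitude_ohm = sig6(ev$amplitude_ohm[j])
        )
      })
    )
  })
  list(n_windows = nrow(analysis), windows = windows)
}

#' @rdname analysis_report
#' @param analysis A `vae_analysis` tibble.
#' @param path Output file path.
#' @export
write_report <- function(analysis, path) {
  jsonlite::write_json(analysis_report(analysis), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

sig6 <- function(x) signif(x, 6)
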