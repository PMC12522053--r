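#' Convert voltage-divider measurements to impedance
#'
#' The measurement circuit drives a known AC voltage through a fixed
#' reference resistor in series with the tissue load. With `v_lead1` the RMS
#' voltage at the generator side and `v_lead2` the RMS voltage between the
#' resistor and the load (both referenced to ground), the load impedance is
#'
#'   Z = (v_lead1 - v_lead2) * r / v_lead2
#'
#' i.e. the voltage dropped across the load scaled by the current inferred
#' from the drop across the resistor. A typical reference resistor for chest
#' impedance work is 100 ohms.
#'
#' @param v_lead1,v_lead2 RMS voltages (volts) at scope leads 1 and 2.
#' @param r Reference resistor value in ohms; must be positive.
#' @return Impedance in ohms (vectorised over all arguments).
#' @examples
#' compute_impedance(2, 1, 100) # 100 ohms: symmetric divider, Z = R
#' @export
compute_impedance <- function(v_lead1, v_lead2, r = 100) {
  if (!is.numeric(r) || length(r) < 1L || any(!is.finite(r)) || any(r <= 0)) {
    stop("invalid configuration: reference resistor `r` must be positive", call. = FALSE)
  }
  v_lead1 <- as.numeric(v_lead1)
  v_lead2 <- as.numeric(v_lead2)
  if (any(v_lead2 == 0)) {
    stop("open circuit / no reference drop: `v_lead2` must be non-zero", call. = FALSE)
  }
  (v_lead1 - v_lead2) * r / v_lead2
}

#' Emulate the instrument's block-averaged sampling
#'
#' The acquisition hardware samples the demodulated signal many times per
#' output tick and stores the block mean (32 samples averaged every 10 ms at
#' the defaults, giving a 100 Hz trace). This reproduces that convention for
#' a raw reading vector; a trailing partial block is dropped rather than
#' padded, so stream ends never contribute biased means.
#'
#' @param values Numeric vector of raw readings (impedance, or voltages
#'   already converted via [compute_impedance()]), in acquisition order.
#' @param block Number of consecutive raw readings averaged per output
#'   sample; must be >= 1.
#' @param tick Output sample interval in seconds (one averaged value per
#'   tick); must be positive.
#' @param meta Metadata list stored on the resulting trace.
#' @return An [impedance_trace()] at `1 / tick` Hz, timestamps starting at 0.
#' @examples
#' emulate_block_average(c(1, 2, 3, 4), block = 2, tick = 0.01)
#' @export
emulate_block_average <- function(values, block = 32, tick = 0.01, meta = list()) {
  if (!is.numeric(block) || length(block) != 1L || block < 1 || block != floor(block)) {
    stop("`block` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(tick) || length(tick) != 1L || tick <= 0) {
    stop("`tick` must be positive", call. = FALSE)
  }
  values <- as.numeric(values)
  n_out <- length(values) %/% block
  meta <- utils::modifyList(list(source = "block_average", block = block), meta)
  if (n_out == 0L) {
    return(impedance_trace(numeric(0), numeric(0), rate_hz = 1 / tick, meta = meta))
  }
  m <- matrix(values[seq_len(n_out * block)], nrow = block)
  z <- colMeans(m)
  impedance_trace((seq_len(n_out) - 1) * tick, z, rate_hz = 1 / tick, meta = meta)
}

#' Read and write impedance trace files
#'
#' Traces are stored as plain CSV with an optional leading metadata header of
#' `# key=value` lines (recognised keys include `rate_hz`, `resistor_ohm`,
#' `source`, `note`; unknown keys are preserved), followed by the column
#' header `time_s,impedance_ohm` and one row per sample printed at full
#' double precision, so a write/read round trip is exact.
#'
#' @param path File path.
#' @return `read_trace()` returns an [impedance_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) {
      stop(sprintf("parse error at line %d: metadata line is not `# key=value`", i), call. = FALSE)
    }
    key <- trimws(substr(kv, 1, eq - 1))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
    i <- i + 1L
  }
  if (i > length(lines) || trimws(lines[i]) != "time_s,impedance_ohm") {
    stop(sprintf("parse error at line %d: expected header `time_s,impedance_ohm`", i), call. = FALSE)
  }
  hdr_line <- i
  data_lines <- lines[-seq_len(i)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rate <- if (!is.null(meta$rate_hz)) meta$rate_hz else 100
  if (length(data_lines) == 0L) {
    return(impedance_trace(numeric(0), numeric(0), rate_hz = rate, meta = meta))
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad_ncol <- which(lengths(parts) != 2L)
  if (length(bad_ncol)) {
    stop(sprintf("parse error at line %d: expected 2 comma-separated fields",
                 hdr_line + bad_ncol[1]), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  bad <- which(!stats::complete.cases(m))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-numeric cell", hdr_line + bad[1]), call. = FALSE)
  }
  if (any(diff(m[, 1]) <= 0)) {
    bad <- which(diff(m[, 1]) <= 0)[1] + 1L
    stop(sprintf("parse error at line %d: timestamps not strictly increasing",
                 hdr_line + bad), call. = FALSE)
  }
  impedance_trace(m[, 1], m[, 2], rate_hz = rate, meta = meta)
}

#' @rdname read_trace
#' @param trace An [impedance_trace()].
#' @export
write_trace <- function(trace, path) {
  meta <- trace_meta(trace)
  meta$rate_hz <- trace_rate(trace)
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    sprintf("# %s=%s", k, v)
  }, character(1))
  rows <- sprintf("%.17g,%.17g", trace$time_s, trace$impedance_ohm)
  writeLines(c(hdr, "time_s,impedance_ohm", rows), path)
  invisible(path)
}

#' Replay a trace as an ordered stream of chunks
#'
#' Splits a trace into consecutive, non-overlapping chunks of
#' `chunk_seconds`, in time order, for feeding [stream_trace()] as if the
#' data arrived live. Concatenating the chunks reproduces the original trace
#' exactly; the final chunk holds any remainder.
#'
#' @param trace An [impedance_trace()].
#' @param chunk_seconds Chunk length in seconds; must be positive.
#' @return A list of `impedance_trace` chunks.
#' @export
replay <- function(trace, chunk_seconds) {
  if (!is.numeric(chunk_seconds) || length(chunk_seconds) != 1L || chunk_seconds <= 0) {
    stop("`chunk_seconds` must be positive", call. = FALSE)
  }
  n <- nrow(trace)
  if (n == 0L) return(list())
  per <- max(1L, as.integer(round(chunk_seconds * trace_rate(trace))))
  starts <- seq.int(1L, n, by = per)
  lapply(starts, function(s) trace_slice(trace, s:min(s + per - 1L, n)))
}
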