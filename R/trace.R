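#' Impedance trace objects
#'
#' An impedance trace is a tibble with columns `time_s` (seconds from
#' recording start) and `impedance_ohm`, carrying the sample rate and
#' free-form provenance metadata as attributes. Timestamps must be strictly
#' increasing and uniformly spaced (to within a relative tolerance of 1e-6);
#' this is what the downstream respiratory and detection code assumes.
#'
#' @param time_s Numeric vector of sample times in seconds.
#' @param impedance_ohm Numeric vector of impedance values in ohms.
#' @param rate_hz Sample rate in Hz. If `NULL`, inferred from the median
#'   spacing of `time_s` (the trace must then have at least two samples).
#' @param meta Named list of provenance metadata (e.g. `source`,
#'   `resistor_ohm`, `note`). Stored as-is and round-tripped by
#'   [write_trace()] / [read_trace()].
#'
#' @return A tibble of class `impedance_trace`.
#' @examples
#' tr <- impedance_trace(seq(0, 1, by = 0.01), 250 + sin(seq(0, 1, by = 0.01)))
#' trace_rate(tr)
#' @export
impedance_trace <- function(time_s, impedance_ohm, rate_hz = NULL, meta = list()) {
  time_s <- as.numeric(time_s)
  impedance_ohm <- as.numeric(impedance_ohm)
  if (length(time_s) != length(impedance_ohm)) {
    stop("`time_s` and `impedance_ohm` must have equal length", call. = FALSE)
  }
  n <- length(time_s)
  if (n == 0L) {
    if (is.null(rate_hz)) rate_hz <- 100
  } else if (n == 1L) {
    if (is.null(rate_hz)) {
      stop("`rate_hz` is required for a single-sample trace", call. = FALSE)
    }
  } else {
    dt <- diff(time_s)
    if (any(dt <= 0)) {
      stop("trace timestamps must be strictly increasing", call. = FALSE)
    }
    dt_med <- stats::median(dt)
    if (any(abs(dt - dt_med) > 1e-6 * dt_med + 1e-12)) {
      stop("trace timestamps must be uniformly spaced", call. = FALSE)
    }
    if (is.null(rate_hz)) rate_hz <- 1 / dt_med
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(impedance_ohm))) {
    stop("impedance values must be finite", call. = FALSE)
  }
  if (!is.list(meta)) stop("`meta` must be a list", call. = FALSE)
  new_impedance_trace(
    tibble::tibble(time_s = time_s, impedance_ohm = impedance_ohm),
    rate_hz = as.numeric(rate_hz), meta = meta
  )
}

new_impedance_trace <- function(df, rate_hz, meta = list()) {
  out <- tibble::as_tibble(df)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "meta") <- meta
  class(out) <- c("impedance_trace", class(tibble::tibble()))
  out
}

#' @rdname impedance_trace
#' @param trace An `impedance_trace`.
#' @export
trace_rate <- function(trace) attr(trace, "rate_hz")

#' @rdname impedance_trace
#' @export
trace_meta <- function(trace) {
  m <- attr(trace, "meta")
  if (is.null(m)) list() else m
}

#' @rdname impedance_trace
#' @export
trace_duration <- function(trace) {
  if (nrow(trace) == 0L) return(0)
  # duration counts the trailing sample interval so concatenated chunks tile
  nrow(trace) / trace_rate(trace)
}

# subset rows keeping trace attributes (dplyr verbs strip them)
trace_slice <- function(trace, idx) {
  new_impedance_trace(
    tibble::tibble(
      time_s = trace$time_s[idx],
      impedance_ohm = trace$impedance_ohm[idx]
    ),
    rate_hz = trace_rate(trace), meta = trace_meta(trace)
  )
}

trace_window <- function(trace, from_s, to_s) {
  t0 <- if (nrow(trace)) trace$time_s[1] else 0
  idx <- which(trace$time_s >= t0 + from_s - 1e-9 & trace$time_s < t0 + to_s - 1e-9)
  trace_slice(trace, idx)
}

#' @export
print.impedance_trace <- function(x, ...) {
  cat(sprintf(
    "<impedance_trace: %d samples @ %g Hz, %.2f s>\n",
    nrow(x), trace_rate(x), trace_duration(x)
  ))
  NextMethod()
}
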