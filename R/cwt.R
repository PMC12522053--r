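# Continuous wavelet transform (Ricker / "Mexican hat") and ridge-line peak
# detection. The respiratory peak finder convolves the demeaned trace with
# Ricker wavelets at scales spanning the plausible breath periods, links
# per-scale maxima into ridge lines across scales, and keeps ridges that
# persist over enough scales with adequate coefficient SNR. This trades a
# little latency for far fewer false peaks than raw extrema on noisy data.

ricker_wavelet <- function(n_points, a) {
  x <- seq_len(n_points) - (n_points + 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (x / a)^2) * exp(-x^2 / (2 * a^2))
}

# rows = scales (ascending), columns = time; same-length FFT convolution
cwt_ricker <- function(x, scales) {
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (k in seq_along(scales)) {
    a <- scales[k]
    npts <- min(n, max(3L, as.integer(2 * ceiling(5 * a) + 1)))
    w <- ricker_wavelet(npts, a)
    full <- stats::convolve(x, rev(w), type = "open")
    off <- (npts - 1L) %/% 2L
    out[k, ] <- full[(off + 1L):(off + n)]
  }
  out
}

# indices of local maxima, each the strict max of its +/- halfwidth window
local_maxima <- function(v, halfwidth) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - halfwidth)
    hi <- min(n, i + halfwidth)
    v[i] >= max(v[lo:hi])
  }, logical(1))
  cand[keep]
}

# scipy-style ridge linking: walk from the largest scale down, connecting
# each ridge's current position to the nearest per-scale maximum within a
# scale-dependent distance; ridges missing from `max_gap` consecutive rows
# are closed. Returns ridges as lists of (row, col) pairs.
link_ridges <- function(maxima_by_row, scales, max_gap = 2L) {
  n_rows <- length(maxima_by_row)
  ridges <- list()
  active <- list() # each: list(rows=, cols=, gap=)
  for (r in seq.int(n_rows, 1L)) {
    cols <- maxima_by_row[[r]]
    max_dist <- max(2, scales[r] / 4)
    used <- rep(FALSE, length(cols))
    if (length(active)) {
      for (j in seq_along(active)) {
        rd <- active[[j]]
        if (length(cols)) {
          d <- abs(cols - rd$cols[length(rd$cols)])
          i <- which.min(d)
          if (length(i) && d[i] <= max_dist && !used[i]) {
            rd$rows <- c(rd$rows, r)
            rd$cols <- c(rd$cols, cols[i])
            rd$gap <- 0L
            used[i] <- TRUE
            active[[j]] <- rd
            next
          }
        }
        rd$gap <- rd$gap + 1L
        active[[j]] <- rd
      }
    }
    closed <- vapply(active, function(rd) rd$gap > max_gap, logical(1))
    if (any(closed)) {
      ridges <- c(ridges, active[closed])
      active <- active[!closed]
    }
    if (any(!used)) {
      for (c0 in cols[!used]) {
        active[[length(active) + 1L]] <- list(rows = r, cols = c0, gap = 0L)
      }
    }
  }
  c(ridges, active)
}

# peak columns from a CWT matrix: ridge length and SNR filters, then the
# position at the smallest scale the ridge reached
cwt_peaks <- function(mat, scales, min_length = NULL, min_snr = 1) {
  if (is.null(min_length)) min_length <- ceiling(length(scales) / 2)
  maxima_by_row <- lapply(seq_along(scales), function(r) {
    local_maxima(mat[r, ], halfwidth = max(2L, as.integer(scales[r] / 4)))
  })
  ridges <- link_ridges(maxima_by_row, scales)
  if (!length(ridges)) return(integer(0))
  noise <- stats::quantile(abs(mat[1, ]), 0.10, names = FALSE)
  keep <- vapply(ridges, function(rd) {
    if (length(rd$rows) < min_length) return(FALSE)
    peak_coef <- max(mat[cbind(rd$rows, rd$cols)])
    peak_coef > 0 && peak_coef / max(noise, 1e-12) >= min_snr
  }, logical(1))
  ridges <- ridges[keep]
  if (!length(ridges)) return(integer(0))
  sort(vapply(ridges, function(rd) rd$cols[which.min(rd$rows)], numeric(1)))
}
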