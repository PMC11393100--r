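#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) plus a residue
#' by iterative envelope sifting: at each sift the mean of the cubic-spline
#' envelopes through the local maxima and minima is subtracted until the
#' candidate satisfies a Cauchy-type convergence criterion. Envelopes use a
#' mirrored-extrema boundary extension so the splines do not fly off at the
#' ends. Extraction proceeds fast to slow; the returned IMFs are reordered
#' slow to fast (`imfs[[1]]` is the slowest mode), with the residue slowest
#' of all, so that trend/fluctuation indexing reads naturally.
#'
#' The decomposition is exact by construction:
#' `Reduce("+", imfs) + residue == y` to floating tolerance.
#'
#' @param y numeric series, length >= 8, all finite.
#' @param sd_thresh Cauchy stop threshold on the normalised squared change
#'   between consecutive sifts (default 0.2, standard practice).
#' @param max_sift maximum sifting iterations per IMF.
#' @param max_imfs maximum number of IMFs to extract.
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors, slow to fast), `residue`, and `n_imfs`. A signal with fewer
#'   than 2 interior extrema yields `n_imfs = 0` and `residue = y`.
#' @export
#' @examples
#' t <- seq_len(512)
#' dec <- emd(sin(2 * pi * t / 32))
#' dec$n_imfs
emd <- function(y, sd_thresh = 0.2, max_sift = 50L, max_imfs = 12L) {
  stopifnot(is.numeric(y), length(y) >= 8, all(is.finite(y)))
  n <- length(y)
  residue <- y
  imfs <- list()
  scale0 <- stats::sd(y)
  if (scale0 == 0) {
    return(structure(list(imfs = list(), residue = y, n_imfs = 0L),
                     class = "imf_set"))
  }
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$max_i) < 2 || length(ext$min_i) < 2) break
    if (stats::sd(residue) < 1e-10 * scale0) break
    h <- residue
    for (k in seq_len(max_sift)) {
      em <- envelope_mean(h)
      if (is.null(em)) break
      h_new <- h - em
      sd_k <- sum((h - h_new)^2) / (sum(h^2) + 1e-300)
      h <- h_new
      if (sd_k < sd_thresh && imf_property_ok(h)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  # extraction order is fast -> slow; reverse to slow -> fast
  structure(list(imfs = rev(imfs), residue = residue,
                 n_imfs = length(imfs)), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d intrinsic mode functions (slow to fast) + residue, n = %d\n",
              x$n_imfs, length(x$residue)))
  invisible(x)
}

# IMF defining property: extrema and zero-crossing counts differ by at
# most one.
imf_property_ok <- function(h) {
  ext <- find_extrema(h)
  n_ext <- length(ext$max_i) + length(ext$min_i)
  nz <- h[h != 0]
  n_zc <- sum(diff(sign(nz)) != 0)
  abs(n_ext - n_zc) <= 1
}

# Local extrema indices of a series; plateaus collapse to their midpoint.
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse exact ties so plateaus register once
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(max_i = integer(), min_i = integer()))
  s <- sign(d[nz])
  turn <- which(diff(s) != 0)
  idx <- nz[turn] + 1L
  kind <- s[turn]             # +1 then down = max; -1 then up = min
  list(max_i = idx[kind > 0], min_i = idx[kind < 0])
}

# Mean of upper/lower cubic-spline envelopes with mirrored-extrema
# extension; NULL when there are too few extrema to continue sifting.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$max_i) < 2 || length(ext$min_i) < 2) return(NULL)
  up <- spline_envelope(ext$max_i, x[ext$max_i], n)
  lo <- spline_envelope(ext$min_i, x[ext$min_i], n)
  (up + lo) / 2
}

# Cubic spline through (idx, val) evaluated on 1..n, with up to two
# extrema mirrored beyond each boundary.
spline_envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  li <- 2 * 1L - rev(idx[seq_len(k)])          # mirror about t = 1
  lv <- rev(val[seq_len(k)])
  m <- length(idx)
  ri <- 2 * n - rev(idx[seq.int(m - k + 1L, m)])
  rv <- rev(val[seq.int(m - k + 1L, m)])
  xs <- c(li, idx, ri)
  ys <- c(lv, val, rv)
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}
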