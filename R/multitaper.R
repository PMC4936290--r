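#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` for half-bandwidth
#' `W = nw/n` by the classic tridiagonal formulation: the tapers are the
#' eigenvectors of the symmetric tridiagonal matrix with diagonal
#' `((n-1-2t)/2)^2 cos(2*pi*W)` and off-diagonal `t(n-t)/2`, ordered by
#' decreasing eigenvalue. Each taper is normalised to unit energy
#' (`sum(v^2) = 1`); symmetric tapers are oriented to have positive mean
#' and antisymmetric ones a positive initial slope.
#'
#' @param n sequence length (>= 8 for spectral use).
#' @param nw time-bandwidth product (typically 3-5).
#' @param k number of tapers, at most `2*nw - 1`.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpssTapers <- function(n, nw = 4, k = 2 * nw - 1) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 2 * nw - 1)
    stop("k = ", k, " exceeds 2*nw - 1 = ", 2 * nw - 1,
         "; higher-order tapers leak badly")
  if (nw >= n / 2) stop("nw must be < n/2")
  t0 <- 0:(n - 1)
  diagv <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * nw / n)
  offv <- t0[-1L] * (n - t0[-1L]) / 2
  A <- matrix(0, n, n)
  A[cbind(t0 + 1, t0 + 1)] <- diagv
  A[cbind(2:n, 1:(n - 1))] <- offv
  A[cbind(1:(n - 1), 2:n)] <- offv
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    if (j %% 2L == 1L) {               # symmetric order: positive mean
      if (sum(v) < 0) v <- -v
    } else {                           # antisymmetric: positive initial slope
      if (sum(v * seq_len(n)) < 0) v <- -v
    }
    V[, j] <- v
  }
  V
}

#' Thomson multitaper power spectral density
#'
#' One-sided PSD estimate of a uniformly sampled series: the plain average
#' of `k` eigenspectra, where eigenspectrum `j` is `dt * |DFT(v_j * x)|^2`
#' with `v_j` the j-th unit-energy DPSS taper. Interior bins (1 to
#' `nfft/2 - 1`) are doubled so the one-sided estimate integrates to the
#' total power. Frequencies are in cycles per minute for `dt` in minutes.
#'
#' @param x numeric series, length >= 8, all finite.
#' @param dt sampling interval, minutes.
#' @param nw time-bandwidth product (default 4).
#' @param k taper count (default `2*nw - 1 = 7`).
#' @param nfft transform length, `>= length(x)`; default next power of two.
#' @param center subtract the series mean first (default `FALSE`; feature
#'   assembly centers explicitly).
#' @param tapers optional taper matrix overriding the DPSS computation
#'   (e.g. a flat window to recover the periodogram).
#' @return A [SpectralEstimate-class] with `nfft/2 + 1` bins from 0 to
#'   Nyquist.
#' @examples
#' ps <- multitaperPSD(sin(2 * pi * 0.1 * (0:63)), dt = 1)
#' ps@frequencies[which.max(ps@psd)]   # ~0.1 cycles/min
#' @export
multitaperPSD <- function(x, dt, nw = 4, k = 2 * nw - 1, nfft = NULL,
                          center = FALSE, tapers = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("series too short for spectral estimation (need >= 8)")
  if (!all(is.finite(x))) stop("non-finite values in series")
  if (is.null(nfft)) nfft <- 2^ceiling(log2(n))
  nfft <- as.integer(nfft)
  if (nfft < n) stop("nfft must be >= length(x)")
  if (center) x <- x - mean(x)
  if (is.null(tapers)) tapers <- dpssTapers(n, nw, k)
  k <- ncol(tapers)
  half <- nfft %/% 2L
  acc <- numeric(half + 1L)
  for (j in seq_len(k)) {
    xt <- c(tapers[, j] * x, numeric(nfft - n))
    sp <- dt * Mod(fft(xt))^2
    acc <- acc + sp[seq_len(half + 1L)]
  }
  psd <- acc / k
  if (half > 1L) psd[2:half] <- 2 * psd[2:half]   # fold negative frequencies
  freqs <- (0:half) / (nfft * dt)
  new("SpectralEstimate", frequencies = freqs, psd = psd, nw = nw,
      k = as.integer(k))
}

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf(
    "SpectralEstimate: %d bins, 0-%.4g cycles/min (nw=%g, k=%d tapers)\n",
    length(object@psd), max(object@frequencies), object@nw, object@k))
  pk <- which.max(object@psd)
  cat(sprintf("  peak %.4g at %.4g cycles/min\n", object@psd[pk],
              object@frequencies[pk]))
})
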