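#' Temporal interaction products of the three hormone curves
#'
#' The elementwise "mixed effect" channels pairing the hormones:
#' `[G*C, G*P, C*P, G*C*P]`, each on the same grid as the inputs.
#'
#' @param g,c,p equal-length finite numeric series (GLP-1, CCK, PYY).
#' @return A 4-row matrix in the order `GC, GP, CP, GCP`.
#' @examples
#' interactionProducts(c(1, 2), c(3, 4), c(5, 6))
#' @export
interactionProducts <- function(g, c, p) {
  if (length(g) != length(c) || length(g) != length(p))
    stop("series lengths differ")
  if (!all(is.finite(g), is.finite(c), is.finite(p)))
    stop("non-finite input")
  rbind(GC = g * c, GP = g * p, CP = c * p, GCP = g * c * p)
}

#' Spectral-feature settings
#'
#' @param nw time-bandwidth product of the DPSS tapers.
#' @param k taper count (`<= 2*nw - 1`).
#' @param nfft transform length; `NULL` = next power of two above the grid
#'   length.
#' @param center mean-center each channel before the PSD so the DC bin does
#'   not dominate the spectral block (temporal features stay raw).
#' @return Settings list for [assembleFeatures()].
#' @export
psdSettings <- function(nw = 4, k = 2 * nw - 1, nfft = NULL, center = TRUE) {
  list(nw = nw, k = as.integer(k), nfft = nfft, center = isTRUE(center))
}

#' Assemble the whole-curve network input for one subject
#'
#' Builds `U = [I(t), M(t), I(w), M(w)]`: the three hormone series and
#' their four interaction products in time, followed by the multitaper PSD
#' of each of the same seven channels. One subject's complete curve set is
#' one training sample; the flattened length is `7*T + 7*F` with
#' `F = nfft/2 + 1`.
#'
#' @param g,c,p hormone series on a shared uniform grid (all three must be
#'   present; imputation happens upstream).
#' @param dt grid step, minutes.
#' @param psd settings from [psdSettings()].
#' @return A [FeatureVector-class].
#' @export
assembleFeatures <- function(g, c, p, dt, psd = psdSettings()) {
  if (any(is.na(g)) || any(is.na(c)) || any(is.na(p)))
    stop("all three hormones must be present; impute missing channels first")
  temporal <- rbind(G = g, C = c, P = p, interactionProducts(g, c, p))
  nfft <- if (is.null(psd$nfft)) 2^ceiling(log2(length(g))) else psd$nfft
  spec <- apply(temporal, 1L, function(ch)
    multitaperPSD(ch, dt = dt, nw = psd$nw, k = psd$k, nfft = nfft,
                  center = psd$center)@psd)
  freqs <- (0:(nfft %/% 2L)) / (nfft * dt)
  new("FeatureVector", temporal = temporal, spectral = t(spec),
      frequencies = freqs)
}

#' @describeIn assembleFeatures flatten a [FeatureVector-class] to the
#'   numeric input vector (temporal block row-major by channel, then
#'   spectral block).
#' @param fv a `FeatureVector`.
#' @export
flattenFeatures <- function(fv) {
  c(as.vector(t(fv@temporal)), as.vector(t(fv@spectral)))
}

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf(
    "FeatureVector: 7 channels x %d time points + 7 x %d frequency bins (length %d)\n",
    ncol(object@temporal), ncol(object@spectral),
    length(flattenFeatures(object))))
})

setMethod("length", "FeatureVector", function(x)
  7L * ncol(x@temporal) + 7L * ncol(x@spectral))
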