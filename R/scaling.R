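#' Fit, apply and invert the log-sigmoid working-range scaling
#'
#' `fitScaling()` learns per-channel (column) min/max from training data
#' and maps each channel linearly onto `[lo, hi]` (default `[0.1, 0.9]`,
#' safely inside the log-sigmoid output range). `applyScaling()` and
#' `invertScaling()` are exact inverses of each other on the fitted range;
#' a channel with zero range maps to the midpoint and inverts back to its
#' constant. With `shared = TRUE` a single global range is used for all
#' channels — required wherever channel identity must not leak through
#' scaling (the identity-free hormone imputer, the lag windows of the
#' series extender).
#'
#' @param x numeric matrix, samples in rows; a vector is treated as one row.
#' @param lo,hi target range bounds.
#' @param shared use one min/max over all channels.
#' @param spec a fitted [ScalingSpec-class].
#' @param clamp clamp scaled values into `[lo, hi]` (`applyScaling`) or
#'   de-scaled values into the fitted bounds (`invertScaling`).
#' @return `fitScaling`: a [ScalingSpec-class]; the others: a matrix shaped
#'   like `x`.
#' @examples
#' s <- fitScaling(matrix(c(0, 100), 2, 1))
#' applyScaling(s, matrix(c(0, 50, 100), 3, 1))
#' @export
fitScaling <- function(x, lo = 0.1, hi = 0.9, shared = FALSE) {
  x <- rbind(x)
  if (!all(is.finite(x))) stop("non-finite values in scaling fit")
  if (shared) {
    mn <- rep(min(x), ncol(x)); mx <- rep(max(x), ncol(x))
  } else {
    mn <- apply(x, 2L, min); mx <- apply(x, 2L, max)
  }
  new("ScalingSpec", min = unname(mn), max = unname(mx), lo = lo, hi = hi,
      shared = shared)
}

#' @rdname fitScaling
#' @export
applyScaling <- function(spec, x, clamp = FALSE) {
  x <- rbind(x)
  if (ncol(x) != length(spec@min)) stop("channel count mismatch")
  rng <- spec@max - spec@min
  mid <- (spec@lo + spec@hi) / 2
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (rng[j] == 0) mid else
      spec@lo + (x[, j] - spec@min[j]) / rng[j] * (spec@hi - spec@lo)
  }
  if (clamp) out <- pmin(pmax(out, spec@lo), spec@hi)
  out
}

#' @rdname fitScaling
#' @export
invertScaling <- function(spec, x, clamp = FALSE) {
  x <- rbind(x)
  if (ncol(x) != length(spec@min)) stop("channel count mismatch")
  if (clamp) x <- pmin(pmax(x, spec@lo), spec@hi)
  rng <- spec@max - spec@min
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (rng[j] == 0) spec@min[j] else
      spec@min[j] + (x[, j] - spec@lo) / (spec@hi - spec@lo) * rng[j]
  }
  out
}
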