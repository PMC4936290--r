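#' @import methods
#' @importFrom stats approx cor fft rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

HORMONES <- c("GLP1", "CCK", "PYY")
VAS_TYPES <- c("desire", "hunger", "fullness", "satiety")
VAS_COLUMNS <- c(desire = "VAS_D", hunger = "VAS_H",
                 fullness = "VAS_F", satiety = "VAS_S")
# Eq-fixed channel ordering used by every feature block
CHANNELS7 <- c("G", "C", "P", "GC", "GP", "CP", "GCP")

#' SatietyStudy: one study arm of a satiety trial
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding, for one study
#' (one food/infusion arm), the plasma satiety-hormone curves and the VAS
#' score curves of all subjects on a shared time grid. Rows are sampling
#' times (minutes since the first sample), columns are subjects, and the
#' seven assays are `GLP1` (pmol/l), `CCK` (pmol/l), `PYY` (pg/ml) and
#' `VAS_D`, `VAS_H`, `VAS_F`, `VAS_S` (desire to eat, hunger, fullness,
#' satiety; 0-100). A hormone that was never measured for a subject is an
#' all-`NA` column in its assay, mirrored by a logical availability flag in
#' `colData` (`avail.GLP1` etc.).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; study-level
#'   metadata (`name`, `route`, `window`, `units`) lives in `metadata()`.
#' @seealso [satietyStudy()], [readStudy()], [simulateStudy()]
#' @export
setClass("SatietyStudy", contains = "SummarizedExperiment")

setValidity("SatietyStudy", function(object) {
  msg <- character()
  t <- rowData(object)$time_min
  if (is.null(t)) msg <- c(msg, "rowData must contain 'time_min'")
  else {
    if (length(t) < 4L) msg <- c(msg, "time grid must have at least 4 points")
    if (any(!is.finite(t))) msg <- c(msg, "time grid must be finite")
    else if (any(diff(t) <= 0)) msg <- c(msg, "time grid must be strictly increasing")
  }
  need <- c(HORMONES, VAS_COLUMNS)
  miss <- setdiff(need, assayNames(object))
  if (length(miss))
    msg <- c(msg, paste("missing assays:", paste(miss, collapse = ", ")))
  if (ncol(object) < 1L) msg <- c(msg, "study must contain at least one subject")
  for (h in intersect(HORMONES, assayNames(object))) {
    a <- assay(object, h)
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, paste(h, "concentrations must be non-negative"))
  }
  for (v in intersect(VAS_COLUMNS, assayNames(object))) {
    a <- assay(object, v)
    if (any(a < 0 | a > 100, na.rm = TRUE))
      msg <- c(msg, paste(v, "scores must lie in [0, 100]"))
  }
  av <- vapply(HORMONES, function(h) hormoneAvailable(object)[h, , drop = TRUE],
               logical(ncol(object)))
  if (ncol(object) == 1L) av <- matrix(av, nrow = 1L)
  if (any(rowSums(matrix(av, ncol = length(HORMONES))) == 0))
    msg <- c(msg, "every subject needs at least one available hormone")
  nm <- metadata(object)$name
  if (is.null(nm) || !nzchar(nm)) msg <- c(msg, "study name must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Feed-forward network parameters
#'
#' Layer weights and biases of a fully connected network with log-sigmoid
#' activation on every layer (`H = logsig(U %*% w1 + b1)`,
#' `Y = logsig(H %*% w2 + b2)`, and so on for deeper stacks). Weights are
#' stored input-major: `weights[[l]]` maps layer `l-1` activations (rows of
#' a sample matrix) to layer `l` pre-activations.
#'
#' @slot weights list of numeric matrices, one per layer.
#' @slot biases list of numeric vectors, one bias per node (a scalar shared
#'   bias is a config choice at training time; it is materialised as a
#'   constant vector here).
#' @slot config the [trainingConfig()] list used to fit the network.
#' @slot history data.frame of per-epoch train/validation MSE.
#' @export
setClass("FeedForwardNet", representation(
  weights = "list", biases = "list", config = "list", history = "data.frame"))

setValidity("FeedForwardNet", function(object) {
  msg <- character()
  L <- length(object@weights)
  if (L < 2L) msg <- c(msg, "need at least one hidden layer (>= 2 weight layers)")
  if (length(object@biases) != L) msg <- c(msg, "one bias vector per weight layer")
  for (l in seq_len(L)) {
    W <- object@weights[[l]]; b <- object@biases[[l]]
    if (!all(is.finite(W)) || !all(is.finite(b)))
      msg <- c(msg, sprintf("layer %d has non-finite parameters", l))
    if (ncol(W) != length(b))
      msg <- c(msg, sprintf("layer %d: ncol(weights) != length(biases)", l))
    if (l > 1L && nrow(W) != ncol(object@weights[[l - 1L]]))
      msg <- c(msg, sprintf("layer %d input dim does not chain", l))
  }
  if (length(msg)) msg else TRUE
})

#' Per-channel linear scaling into the log-sigmoid working range
#'
#' Affine map of each data channel onto `[lo, hi]` (default `[0.1, 0.9]`)
#' fitted on training data only, with exact inversion. Channels with zero
#' range are mapped to the midpoint and inverted back to the constant.
#'
#' @slot min,max per-channel bounds observed at fit time.
#' @slot lo,hi target range.
#' @slot shared single range shared across all channels (used where channel
#'   identity must not leak through scaling).
#' @export
setClass("ScalingSpec", representation(
  min = "numeric", max = "numeric", lo = "numeric", hi = "numeric",
  shared = "logical"))

#' Assembled network input for one subject
#'
#' The whole-curve input vector `U = [I(t), M(t), I(w), M(w)]`: seven
#' temporal channels (three hormones plus their four interaction products)
#' and the seven matching multitaper PSD channels, in the fixed channel
#' order G, C, P, G*C, G*P, C*P, G*C*P.
#'
#' @slot temporal 7 x T matrix (channels x grid points).
#' @slot spectral 7 x F matrix (channels x frequency bins).
#' @slot frequencies frequency grid, cycles/min.
#' @export
setClass("FeatureVector", representation(
  temporal = "matrix", spectral = "matrix", frequencies = "numeric"))

setValidity("FeatureVector", function(object) {
  msg <- character()
  if (nrow(object@temporal) != 7L || nrow(object@spectral) != 7L)
    msg <- c(msg, "temporal and spectral blocks must have 7 channels")
  if (ncol(object@spectral) != length(object@frequencies))
    msg <- c(msg, "spectral block width must match frequency grid")
  if (!all(is.finite(object@temporal)) || !all(is.finite(object@spectral)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' One-sided multitaper power spectral density estimate
#'
#' @slot frequencies strictly increasing grid from 0 to Nyquist, cycles/min;
#'   length `nfft/2 + 1`.
#' @slot psd non-negative power density per frequency.
#' @slot nw,k time-bandwidth product and taper count used.
#' @export
setClass("SpectralEstimate", representation(
  frequencies = "numeric", psd = "numeric", nw = "numeric", k = "integer"))

setValidity("SpectralEstimate", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@psd))
    msg <- c(msg, "frequencies and psd must have equal length")
  if (any(object@psd < 0)) msg <- c(msg, "psd must be non-negative")
  if (length(object@frequencies) > 1 && any(diff(object@frequencies) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Missing-hormone imputation network
#'
#' Maps any single hormone curve (length T, identity-free) to the full
#' (GLP-1, CCK, PYY) curve set (length 3T). Input scaling is a single
#' range shared over all three hormones so the network cannot infer the
#' input's identity from its magnitude.
#'
#' @slot net the underlying [FeedForwardNet-class].
#' @slot scalingIn,scalingOut [ScalingSpec-class] objects.
#' @slot gridLength T, the grid length the model was trained for.
#' @export
setClass("HormoneImputer", representation(
  net = "FeedForwardNet", scalingIn = "ScalingSpec",
  scalingOut = "ScalingSpec", gridLength = "integer"))

#' Autoregressive series-extension network
#'
#' Learns `X(t)` from the trailing lag window `X(t-L), ..., X(t-1)` and
#' extends a short series closed-loop to a prescribed length.
#'
#' @slot net the underlying [FeedForwardNet-class].
#' @slot lag window length L (steps).
#' @slot scaling shared-range [ScalingSpec-class] (inputs and output are the
#'   same physical variable).
#' @slot channel hormone name the model was trained on (informative).
#' @export
setClass("NarxModel", representation(
  net = "FeedForwardNet", lag = "integer", scaling = "ScalingSpec",
  channel = "character"))

#' VAS prediction model
#'
#' The end-to-end regression from a subject's whole hormone curve set to the
#' four whole VAS curves: features `U = [I(t), M(t), I(w), M(w)]` in, the
#' concatenated desire/hunger/fullness/satiety curves out.
#'
#' @slot net the underlying [FeedForwardNet-class].
#' @slot scalingIn per-feature [ScalingSpec-class]; output scaling is the
#'   fixed VAS range 0-100.
#' @slot scalingOut [ScalingSpec-class] for the VAS block.
#' @slot grid canonical time grid (minutes) the model expects.
#' @slot psd PSD settings list from [psdSettings()].
#' @export
setClass("VasModel", representation(
  net = "FeedForwardNet", scalingIn = "ScalingSpec", scalingOut = "ScalingSpec",
  grid = "numeric", psd = "list"))

#' Evaluation of predicted against measured VAS curves
#'
#' Pearson correlation per VAS type between the subject-averaged predicted
#' and measured curves, plus their mean.
#'
#' @slot r named numeric, one correlation per VAS type (`NA` where the
#'   averaged measured curve has zero variance).
#' @slot average mean of the four correlations.
#' @slot nSubjects number of subjects averaged.
#' @slot study study name.
#' @export
setClass("EvaluationReport", representation(
  r = "numeric", average = "numeric", nSubjects = "integer", study = "character"))

setValidity("EvaluationReport", function(object) {
  ok <- is.na(object@r) | (object@r >= -1 & object@r <= 1)
  if (!all(ok)) "correlations must lie in [-1, 1]" else TRUE
})
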