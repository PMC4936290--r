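#' Train an autoregressive series-extension network
#'
#' Learns the one-step map from the trailing lag window
#' `[X(t-L), ..., X(t-1)]` to `X(t)` on a pool of hormone curves, all on
#' the same uniform grid. Each series of length `n` contributes `n - L`
#' training pairs. The default input is the full lag window; `singleLag =
#' TRUE` restricts it to the single value `X(t-L)`.
#'
#' @param series a numeric vector or list of vectors (one hormone channel's
#'   curves, e.g. one column per subject); every series must be longer than
#'   `L + 2`.
#' @param L lag, in grid steps (default 2).
#' @param config a [trainingConfig()]; the extender uses one hidden layer
#'   of 10 by default.
#' @param channel label stored for bookkeeping.
#' @param singleLag use only `X(t-L)` as input (the minimal autoregressive
#'   form) instead of the full window.
#' @return A [NarxModel-class].
#' @export
trainNarx <- function(series, L = 2, config = trainingConfig(hidden = 10),
                      channel = "", singleLag = FALSE) {
  if (!is.list(series)) series <- list(series)
  L <- as.integer(L)
  if (L < 1L) stop("lag must be >= 1")
  if (any(vapply(series, length, integer(1L)) < L + 3L))
    stop("every series must be longer than L + 2")
  p <- narxPairs(series, L, singleLag)
  # one shared range over window and target: same physical variable
  rng <- range(c(p$X, p$Y))
  sc <- new("ScalingSpec", min = rep(rng[1L], ncol(p$X)),
            max = rep(rng[2L], ncol(p$X)), lo = 0.1, hi = 0.9, shared = TRUE)
  scY <- new("ScalingSpec", min = rng[1L], max = rng[2L], lo = 0.1, hi = 0.9,
             shared = TRUE)
  net <- nnTrain(applyScaling(sc, p$X), applyScaling(scY, p$Y), config)
  new("NarxModel", net = net, lag = L, scaling = sc, channel = channel)
}

narxPairs <- function(series, L, singleLag = FALSE) {
  X <- list(); Y <- list()
  for (s in series) {
    n <- length(s)
    idx <- (L + 1L):n
    win <- do.call(rbind, lapply(idx, function(t)
      if (singleLag) s[t - L] else s[(t - L):(t - 1L)]))
    X[[length(X) + 1L]] <- win
    Y[[length(Y) + 1L]] <- matrix(s[idx], ncol = 1L)
  }
  list(X = do.call(rbind, X), Y = do.call(rbind, Y))
}

#' Extend a series closed-loop to a prescribed length
#'
#' Appends one-step predictions, each computed from the trailing window of
#' observed and previously predicted values, until the series reaches
#' `targetLength`. The observed prefix is returned untouched; appended
#' values are clamped to the training value range (the scaling bounds), so
#' a learned contraction stays bounded.
#'
#' @param model a [NarxModel-class].
#' @param x observed series, length >= the model lag.
#' @param targetLength requested total length, `> length(x)`.
#' @return Numeric vector of length `targetLength`.
#' @export
extendSeries <- function(model, x, targetLength) {
  x <- as.numeric(x)
  L <- model@lag
  if (length(x) < L) stop("series shorter than the model lag")
  if (targetLength <= length(x))
    stop("targetLength must exceed the current length")
  singleLag <- nrow(model@net@weights[[1L]]) == 1L && L > 1L
  scY <- new("ScalingSpec", min = model@scaling@min[1L],
             max = model@scaling@max[1L], lo = model@scaling@lo,
             hi = model@scaling@hi, shared = TRUE)
  out <- x
  while (length(out) < targetLength) {
    n <- length(out)
    win <- if (singleLag) out[n - L + 1L] else out[(n - L + 1L):n]
    u <- applyScaling(model@scaling, matrix(win, nrow = 1L), clamp = TRUE)
    y <- invertScaling(scY, nnForward(model@net, u), clamp = TRUE)
    out <- c(out, y[1L, 1L])
  }
  out
}

#' Extend all hormone channels of a study onto a longer grid
#'
#' Brings a study whose sampling stops early onto the canonical model grid
#' by closed-loop autoregressive extension of every available hormone
#' channel; VAS channels are untouched (they are predicted downstream, not
#' extended). The grid step must match the models' training grid.
#'
#' @param models named list of [NarxModel-class] objects (`GLP1`, `CCK`,
#'   `PYY`), typically from [trainNarxModels()].
#' @param study a [SatietyStudy-class].
#' @param target full target grid (minutes); must extend the study grid on
#'   the same step.
#' @return The study on the target grid, extension recorded in provenance.
#' @export
extendStudy <- function(models, study, target) {
  src <- timeGrid(study)
  target <- as.numeric(target)
  if (length(target) <= length(src)) return(study)
  if (!isTRUE(all.equal(target[seq_along(src)], src)))
    stop("target grid must extend the study grid on the same step")
  av <- hormoneAvailable(study)
  a <- list()
  for (h in HORMONES) {
    m <- assay(study, h)
    ext <- matrix(NA_real_, length(target), ncol(m))
    for (j in seq_len(ncol(m))) {
      if (!av[h, j]) next
      if (is.null(models[[h]])) stop("no extender model for channel ", h)
      ext[, j] <- extendSeries(models[[h]], m[, j], length(target))
    }
    a[[h]] <- pmax(ext, 0)
  }
  vas <- if (hasVAS(study)) {
    lapply(setNames(VAS_TYPES, VAS_TYPES), function(v) {
      m <- matrix(NA_real_, length(target), ncol(study))
      m[seq_along(src), ] <- vasMatrix(study, v)
      m
    })
  }
  out <- satietyStudy(target, glp1 = a$GLP1, cck = a$CCK, pyy = a$PYY,
                      vas = vas, name = studyName(study),
                      route = metadata(study)$route,
                      window = metadata(study)$window,
                      subjects = colnames(study),
                      units = unlist(metadata(study)$units))
  metadata(out)$provenance <- c(metadata(study)$provenance,
                                list(extended = list(
                                  from = max(src), to = max(target),
                                  channels = HORMONES[rowSums(av) > 0])))
  out
}

#' Train one extender per hormone channel on a set of studies
#'
#' @param studies a [SatietyStudy-class] or list of them.
#' @param L lag in grid steps.
#' @param config a [trainingConfig()].
#' @return Named list of [NarxModel-class] (only channels with data).
#' @export
trainNarxModels <- function(studies, L = 2, config = trainingConfig(hidden = 10)) {
  if (is(studies, "SatietyStudy")) studies <- list(studies)
  models <- list()
  for (h in HORMONES) {
    curves <- list()
    for (st in studies) {
      av <- hormoneAvailable(st)
      for (j in which(av[h, ]))
        curves[[length(curves) + 1L]] <- assay(st, h)[, j]
    }
    if (length(curves))
      models[[h]] <- trainNarx(curves, L = L, config = config, channel = h)
  }
  models
}

setMethod("show", "NarxModel", function(object) {
  cat(sprintf("NarxModel%s: lag %d window -> next value\n",
              if (nzchar(object@channel))
                paste0(" [", object@channel, "]") else "",
              object@lag))
  show(object@net)
})
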