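scalingToList <- function(s)
  list(min = s@min, max = s@max, lo = s@lo, hi = s@hi, shared = s@shared)
scalingFromList <- function(l)
  new("ScalingSpec", min = as.numeric(l$min), max = as.numeric(l$max),
      lo = l$lo, hi = l$hi, shared = isTRUE(l$shared))

netToList <- function(net)
  list(sizes = c(nrow(net@weights[[1L]]),
                 vapply(net@weights, ncol, integer(1L))),
       weights = lapply(net@weights, function(w) as.numeric(w)),
       biases = net@biases, config = net@config)

netFromList <- function(l) {
  sizes <- as.integer(unlist(l$sizes))
  W <- vector("list", length(sizes) - 1L)
  for (i in seq_along(W))
    W[[i]] <- matrix(as.numeric(unlist(l$weights[[i]])), sizes[i],
                     sizes[i + 1L])
  new("FeedForwardNet", weights = W,
      biases = lapply(l$biases, function(b) as.numeric(unlist(b))),
      config = l$config, history = data.frame())
}

#' Save and load trained models as plain-text JSON
#'
#' Persists layer shapes, weights, biases, scaling specs and the training
#' config of a [FeedForwardNet-class], [HormoneImputer-class],
#' [NarxModel-class] or [VasModel-class]. The file is a plain JSON
#' document with full numeric precision.
#'
#' @param model the model object.
#' @param path output `.json` path.
#' @return `writeModel`: `path`, invisibly; `readModel`: the restored
#'   model.
#' @export
writeModel <- function(model, path) {
  l <- if (is(model, "FeedForwardNet")) {
    list(class = "FeedForwardNet", net = netToList(model))
  } else if (is(model, "HormoneImputer")) {
    list(class = "HormoneImputer", net = netToList(model@net),
         scalingIn = scalingToList(model@scalingIn),
         scalingOut = scalingToList(model@scalingOut),
         gridLength = model@gridLength)
  } else if (is(model, "NarxModel")) {
    list(class = "NarxModel", net = netToList(model@net), lag = model@lag,
         scaling = scalingToList(model@scaling), channel = model@channel)
  } else if (is(model, "VasModel")) {
    list(class = "VasModel", net = netToList(model@net),
         scalingIn = scalingToList(model@scalingIn),
         scalingOut = scalingToList(model@scalingOut), grid = model@grid,
         psd = model@psd)
  } else stop("unsupported model class: ", class(model))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- netFromList(l$net)
  switch(l$class,
    FeedForwardNet = net,
    HormoneImputer = new("HormoneImputer", net = net,
                         scalingIn = scalingFromList(l$scalingIn),
                         scalingOut = scalingFromList(l$scalingOut),
                         gridLength = as.integer(l$gridLength)),
    NarxModel = new("NarxModel", net = net, lag = as.integer(l$lag),
                    scaling = scalingFromList(l$scaling),
                    channel = l$channel),
    VasModel = {
      psd <- l$psd
      psd$k <- as.integer(psd$k)
      new("VasModel", net = net, scalingIn = scalingFromList(l$scalingIn),
          scalingOut = scalingFromList(l$scalingOut),
          grid = as.numeric(l$grid), psd = psd)
    },
    stop("unknown model class in file: ", l$class))
}
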