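#' Log-sigmoid activation
#'
#' `1 / (1 + exp(-x))`, elementwise. The bounded activation applied on
#' every layer of the networks in this package; saturates without
#' overflowing for any finite input.
#'
#' @param x numeric vector, matrix or scalar.
#' @return Values in (0, 1), same shape as `x`.
#' @examples
#' logsig(0)            # 0.5
#' logsig(c(-5, 0, 5))
#' @export
logsig <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the feed-forward networks
#'
#' @param hidden hidden-layer widths; the VAS and imputation networks use
#'   two hidden layers by default.
#' @param maxEpochs full-batch epochs budget.
#' @param algorithm `"rprop"` (resilient backpropagation, the default:
#'   deterministic sign-based steps, no learning-rate tuning) or `"gdm"`
#'   (gradient descent with momentum).
#' @param learningRate,momentum `"gdm"` parameters.
#' @param valFraction fraction of samples held out for early stopping,
#'   in (0, 1).
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for the weight init and the train/validation split;
#'   must be explicit so training is reproducible.
#' @param sharedBias tie all biases of a layer to one scalar (the literal
#'   reading of a single scalar bias per layer); default is one bias per
#'   node.
#' @return A config list consumed by [nnTrain()].
#' @export
trainingConfig <- function(hidden = c(10, 10), maxEpochs = 4000,
                           algorithm = c("rprop", "gdm"),
                           learningRate = 0.1, momentum = 0.9,
                           valFraction = 0.2, patience = 100, seed = 1,
                           sharedBias = FALSE) {
  stopifnot(valFraction > 0, valFraction < 1, patience >= 1,
            maxEpochs >= 1, all(hidden >= 1), length(seed) == 1L)
  list(hidden = as.integer(hidden), maxEpochs = as.integer(maxEpochs),
       algorithm = match.arg(algorithm), learningRate = learningRate,
       momentum = momentum, valFraction = valFraction,
       patience = as.integer(patience), seed = as.integer(seed),
       sharedBias = isTRUE(sharedBias))
}

# Evaluate `expr` under a private RNG stream; the caller's stream is untouched.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

nnInit <- function(sizes, seed) {
  withLocalSeed(seed, {
    L <- length(sizes) - 1L
    weights <- biases <- vector("list", L)
    for (l in seq_len(L)) {
      fanIn <- sizes[l]
      lim <- 1 / sqrt(fanIn)
      weights[[l]] <- matrix(runif(fanIn * sizes[l + 1L], -lim, lim),
                             fanIn, sizes[l + 1L])
      biases[[l]] <- runif(sizes[l + 1L], -lim, lim)
    }
    list(weights = weights, biases = biases)
  })
}

#' Forward pass of a log-sigmoid feed-forward network
#'
#' Applies `A <- logsig(A %*% W_l + b_l)` layer by layer. Inputs are
#' expected in the scaled working range; every output component lies
#' strictly in (0, 1).
#'
#' @param net a [FeedForwardNet-class].
#' @param u input vector, or matrix with one sample per row.
#' @return Matrix of outputs, one sample per row.
#' @export
nnForward <- function(net, u) {
  A <- rbind(u)
  if (ncol(A) != nrow(net@weights[[1L]]))
    stop("input length ", ncol(A), " does not match network input dim ",
         nrow(net@weights[[1L]]))
  for (l in seq_along(net@weights))
    A <- logsig(sweep(A %*% net@weights[[l]], 2L, net@biases[[l]], `+`))
  A
}

# Full-batch loss and gradient by backpropagation.
# Loss = mean over all entries of (Y - T)^2.
nnGradient <- function(weights, biases, X, T) {
  L <- length(weights)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L))
    A[[l + 1L]] <- logsig(sweep(A[[l]] %*% weights[[l]], 2L, biases[[l]], `+`))
  Y <- A[[L + 1L]]
  nTot <- length(Y)
  loss <- sum((Y - T)^2) / nTot
  dW <- dB <- vector("list", L)
  dA <- 2 * (Y - T) / nTot
  for (l in rev(seq_len(L))) {
    dZ <- dA * A[[l + 1L]] * (1 - A[[l + 1L]])
    dW[[l]] <- crossprod(A[[l]], dZ)
    dB[[l]] <- colSums(dZ)
    if (l > 1L) dA <- dZ %*% t(weights[[l]])
  }
  list(loss = loss, dW = dW, dB = dB)
}

nnLoss <- function(weights, biases, X, T) {
  A <- X
  for (l in seq_along(weights))
    A <- logsig(sweep(A %*% weights[[l]], 2L, biases[[l]], `+`))
  sum((A - T)^2) / length(A)
}

#' Train a feed-forward network by backpropagation with early stopping
#'
#' Full-batch minimisation of mean squared error. Samples are split at
#' random (by `config$seed`) into a training and a validation part; the
#' parameters with the lowest validation MSE seen so far are kept, and
#' training stops after `config$patience` epochs without improvement.
#' Identical `(samples, config)` reproduce identical parameters.
#'
#' @param X input matrix, one sample per row, pre-scaled into the working
#'   range.
#' @param Y target matrix, one sample per row, pre-scaled into (0, 1).
#' @param config a [trainingConfig()] list.
#' @return A [FeedForwardNet-class] with the training history attached.
#' @export
nnTrain <- function(X, Y, config = trainingConfig()) {
  X <- rbind(X); Y <- rbind(Y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples")
  if (nrow(Y) != n) stop("X and Y sample counts differ")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite samples")
  sizes <- c(ncol(X), config$hidden, ncol(Y))

  nVal <- max(1L, round(config$valFraction * n))
  if (n - nVal < 2L) stop("fewer samples than the validation split allows")
  split <- withLocalSeed(config$seed + 1L, sample.int(n, nVal))
  Xt <- X[-split, , drop = FALSE]; Yt <- Y[-split, , drop = FALSE]
  Xv <- X[split, , drop = FALSE];  Yv <- Y[split, , drop = FALSE]

  par <- nnInit(sizes, config$seed)
  W <- par$weights; B <- par$biases
  L <- length(W)
  if (config$sharedBias)
    B <- lapply(B, function(b) rep(mean(b), length(b)))

  # optimizer state
  vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)
  gW <- vW; gB <- vB                       # previous-epoch gradients (rprop)
  sW <- lapply(W, function(w) w * 0 + 0.01) # rprop step sizes
  sB <- lapply(B, function(b) b * 0 + 0.01)

  best <- list(W = W, B = B, val = Inf, epoch = 0L)
  hist <- matrix(NA_real_, config$maxEpochs, 2L,
                 dimnames = list(NULL, c("train", "validation")))
  sinceBest <- 0L

  for (epoch in seq_len(config$maxEpochs)) {
    g <- nnGradient(W, B, Xt, Yt)
    if (!is.finite(g$loss)) stop("training diverged (non-finite loss)")
    if (config$sharedBias)
      g$dB <- lapply(g$dB, function(d) rep(sum(d), length(d)))

    if (config$algorithm == "rprop") {
      for (l in seq_len(L)) {
        sgn <- sign(g$dW[[l]] * gW[[l]])
        sW[[l]] <- pmin(pmax(sW[[l]] * ifelse(sgn > 0, 1.2,
                                              ifelse(sgn < 0, 0.5, 1)),
                             1e-9), 1)
        g$dW[[l]][sgn < 0] <- 0           # iRprop-: skip after sign flip
        W[[l]] <- W[[l]] - sign(g$dW[[l]]) * sW[[l]]
        gW[[l]] <- g$dW[[l]]
        sgnB <- sign(g$dB[[l]] * gB[[l]])
        sB[[l]] <- pmin(pmax(sB[[l]] * ifelse(sgnB > 0, 1.2,
                                              ifelse(sgnB < 0, 0.5, 1)),
                             1e-9), 1)
        g$dB[[l]][sgnB < 0] <- 0
        B[[l]] <- B[[l]] - sign(g$dB[[l]]) * sB[[l]]
        gB[[l]] <- g$dB[[l]]
      }
    } else {                              # gradient descent with momentum
      for (l in seq_len(L)) {
        vW[[l]] <- config$momentum * vW[[l]] - config$learningRate * g$dW[[l]]
        vB[[l]] <- config$momentum * vB[[l]] - config$learningRate * g$dB[[l]]
        W[[l]] <- W[[l]] + vW[[l]]
        B[[l]] <- B[[l]] + vB[[l]]
      }
    }

    val <- nnLoss(W, B, Xv, Yv)
    hist[epoch, ] <- c(g$loss, val)
    if (val < best$val) {
      best <- list(W = W, B = B, val = val, epoch = epoch)
      sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (sinceBest >= config$patience) break
  }

  hist <- hist[seq_len(epoch), , drop = FALSE]
  new("FeedForwardNet", weights = best$W, biases = best$B, config = config,
      history = data.frame(epoch = seq_len(epoch), train = hist[, 1L],
                           validation = hist[, 2L]))
}

setMethod("show", "FeedForwardNet", function(object) {
  sizes <- c(nrow(object@weights[[1L]]),
             vapply(object@weights, ncol, integer(1L)))
  cat("FeedForwardNet ", paste(sizes, collapse = "-"),
      " (log-sigmoid)\n", sep = "")
  if (nrow(object@history)) {
    b <- which.min(object@history$validation)
    cat(sprintf("  trained %d epochs, best validation MSE %.3g at epoch %d\n",
                nrow(object@history), object@history$validation[b], b))
  }
})
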