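test_that("logsig has the textbook values and symmetry", {
  expect_identical(logsig(0), 0.5)
  for (x in c(-5, -1, 2, 8))
    expect_equal(logsig(x) + logsig(-x), 1, tolerance = 1e-15)
  expect_equal(logsig(1), 0.731058578630004896, tolerance = 1e-12)
  expect_equal(logsig(1000), 1)   # saturates, no overflow
  expect_equal(logsig(-1000), 0)
})

test_that("forward pass equals an explicit per-node scalar loop", {
  # zero parameters: every output is logsig(0)
  zero <- new("FeedForwardNet",
              weights = list(matrix(0, 3, 4), matrix(0, 4, 2)),
              biases = list(rep(0, 4), rep(0, 2)),
              config = list(), history = data.frame())
  expect_equal(as.numeric(nnForward(zero, c(1, -2, 5))), rep(0.5, 2))

  # 1-1-1 hand evaluation
  one <- new("FeedForwardNet",
             weights = list(matrix(1), matrix(1)),
             biases = list(0, 0), config = list(), history = data.frame())
  expect_equal(as.numeric(nnForward(one, 1)), logsig(logsig(1)),
               tolerance = 1e-15)

  set.seed(8)
  sizes <- c(5, 7, 7, 3)
  par <- satiecast:::nnInit(sizes, 2)
  net <- new("FeedForwardNet", weights = par$weights, biases = par$biases,
             config = list(), history = data.frame())
  u <- runif(5)
  # scalar loop over nodes, no matrix algebra
  a <- u
  for (l in 1:3) {
    nxt <- numeric(sizes[l + 1])
    for (j in seq_len(sizes[l + 1])) {
      z <- par$biases[[l]][j]
      for (i in seq_len(sizes[l])) z <- z + a[i] * par$weights[[l]][i, j]
      nxt[j] <- 1 / (1 + exp(-z))
    }
    a <- nxt
  }
  expect_equal(as.numeric(nnForward(net, u)), a, tolerance = 1e-12)
  expect_error(nnForward(net, runif(4)), "does not match")
})

test_that("backprop gradient matches central finite differences", {
  set.seed(42)
  X <- matrix(runif(40), 10, 4)
  Y <- matrix(runif(20), 10, 2)
  par <- satiecast:::nnInit(c(4, 5, 5, 2), 3)
  g <- satiecast:::nnGradient(par$weights, par$biases, X, Y)
  h <- 1e-5
  relErr <- function(num, ana) abs(num - ana) / max(abs(num), 1e-10)
  worst <- 0
  for (l in 1:3) {
    for (i in seq_along(par$weights[[l]])) {
      wp <- par$weights; wp[[l]][i] <- wp[[l]][i] + h
      wm <- par$weights; wm[[l]][i] <- wm[[l]][i] - h
      num <- (satiecast:::nnLoss(wp, par$biases, X, Y) -
                satiecast:::nnLoss(wm, par$biases, X, Y)) / (2 * h)
      worst <- max(worst, relErr(num, g$dW[[l]][i]))
    }
    for (i in seq_along(par$biases[[l]])) {
      bp <- par$biases; bp[[l]][i] <- bp[[l]][i] + h
      bm <- par$biases; bm[[l]][i] <- bm[[l]][i] - h
      num <- (satiecast:::nnLoss(par$weights, bp, X, Y) -
                satiecast:::nnLoss(par$weights, bm, X, Y)) / (2 * h)
      worst <- max(worst, relErr(num, g$dB[[l]][i]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("scaling maps to [0.1, 0.9], inverts exactly and guards constants", {
  s <- fitScaling(matrix(c(0, 100), 2, 1))
  expect_equal(as.numeric(applyScaling(s, matrix(c(0, 100), 2, 1))),
               c(0.1, 0.9))
  expect_equal(as.numeric(invertScaling(s, applyScaling(s, matrix(c(0, 37.5, 100))))),
               c(0, 37.5, 100))

  const <- fitScaling(matrix(5, 3, 1))
  expect_equal(as.numeric(applyScaling(const, matrix(c(5, 5)))), c(0.5, 0.5))
  expect_equal(as.numeric(invertScaling(const, matrix(c(0.5, 0.2)))), c(5, 5))

  set.seed(6)
  x <- matrix(rnorm(60, sd = 40), 10, 6)
  s2 <- fitScaling(x)
  expect_lt(max(abs(invertScaling(s2, applyScaling(s2, x)) - x)), 1e-12)
  sh <- fitScaling(x, shared = TRUE)
  expect_identical(sh@min, rep(min(x), 6))
  expect_error(fitScaling(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("training fits known generating functions with early stopping", {
  withr::with_seed(5, {
    Xc <- matrix(runif(200), 50, 4)
  })
  netc <- nnTrain(Xc, matrix(0.7, 50, 1), trainingConfig(seed = 2))
  withr::with_seed(6, Xnew <- matrix(runif(40), 10, 4))
  expect_lt(max(abs(nnForward(netc, Xnew) - 0.7)), 0.02)

  withr::with_seed(7, U <- matrix(runif(400, 0.1, 0.9), 200, 2))
  Yl <- matrix(logsig(2 * U[, 1] - U[, 2]), ncol = 1)
  net <- nnTrain(U[1:150, ], Yl[1:150, , drop = FALSE],
                 trainingConfig(seed = 1))
  expect_lt(mean((nnForward(net, U[151:200, ]) - Yl[151:200, ])^2), 1e-3)

  # outputs strictly in (0, 1)
  out <- nnForward(net, U)
  expect_true(all(out > 0 & out < 1))

  # accepted early-stopping checkpoints are non-increasing in validation MSE
  acc <- cummin(net@history$validation)
  expect_true(all(diff(acc) <= 0))

  expect_error(nnTrain(U[1:3, ], Yl[1:3, , drop = FALSE]), "at least 4")
})

test_that("training is reproducible and the gdm variant converges too", {
  withr::with_seed(9, {
    X <- matrix(runif(80), 20, 4)
    Y <- matrix(runif(20, 0.2, 0.8), 20, 1)
  })
  cfg <- trainingConfig(hidden = 5, maxEpochs = 300, seed = 11)
  a <- nnTrain(X, Y, cfg)
  b <- nnTrain(X, Y, cfg)
  expect_identical(a@weights, b@weights)
  expect_identical(a@biases, b@biases)

  gd <- nnTrain(X, Y, trainingConfig(hidden = 5, algorithm = "gdm",
                                     maxEpochs = 500, seed = 11))
  expect_true(all(is.finite(unlist(gd@weights))))
  # shared-bias variant ties each layer's biases to one scalar
  sb <- nnTrain(X, Y, trainingConfig(hidden = 5, maxEpochs = 100, seed = 1,
                                     sharedBias = TRUE))
  for (b1 in sb@biases) expect_lt(diff(range(b1)), 1e-12)
})

test_that("models survive a JSON round trip", {
  withr::with_seed(3, {
    X <- matrix(runif(80), 20, 4)
    Y <- matrix(runif(40, 0.2, 0.8), 20, 2)
  })
  net <- nnTrain(X, Y, trainingConfig(hidden = 6, maxEpochs = 50, seed = 4))
  p <- file.path(withr::local_tempdir(), "net.json")
  writeModel(net, p)
  back <- readModel(p)
  expect_equal(back@weights, net@weights, tolerance = 1e-12)
  expect_equal(nnForward(back, X), nnForward(net, X), tolerance = 1e-12)
})
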