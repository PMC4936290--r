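test_that("interaction products equal a scalar loop and annihilate on zeros", {
  m <- interactionProducts(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(unname(m), rbind(c(3, 8), c(5, 12), c(15, 24), c(15, 48)))

  set.seed(21)
  g <- runif(25); c <- runif(25); p <- runif(25)
  loop <- matrix(0, 4, 25)
  for (i in 1:25)
    loop[, i] <- c(g[i] * c[i], g[i] * p[i], c[i] * p[i], g[i] * c[i] * p[i])
  expect_equal(unname(interactionProducts(g, c, p)), loop,
               tolerance = 1e-15)

  zc <- interactionProducts(g, rep(0, 25), p)
  expect_true(all(zc["GCP", ] == 0) && all(zc["GC", ] == 0))
  # symmetry under relabeling within a product
  expect_identical(g * c, c * g)
  expect_error(interactionProducts(g, c[-1], p), "lengths differ")
  expect_error(interactionProducts(g, c, replace(p, 3, NA)), "non-finite")
})

test_that("DPSS tapers match the reference eigen-sequences and are unit energy", {
  V <- dpssTapers(16, nw = 4, k = 7)
  expect_equal(colSums(V^2), rep(1, 7), tolerance = 1e-12)
  # frozen from scipy.signal.windows.dpss(16, 4, 7) (sign-free comparison;
  # the antisymmetric tapers' sign is conventional)
  ref1 <- c(0.000839443, 0.0065515295, 0.0269425302, 0.0761717523,
            0.1638876965, 0.2823629404, 0.400703128, 0.4756861708)
  ref2 <- c(0.0044223139, 0.0282940524, 0.0946090707, 0.2124981382,
            0.3479949215, 0.4217684772, 0.3556254405, 0.140053515)
  ref7 <- c(0.3935595476, 0.3953136553, 0.0018835894, -0.2830872456,
            -0.0903894709, 0.2222964126, 0.1386788138, -0.1785449383)
  cmp <- function(v, ref) min(max(abs(v - ref)), max(abs(v + ref)))
  expect_lt(cmp(V[1:8, 1], ref1), 1e-8)
  expect_lt(cmp(V[1:8, 2], ref2), 1e-8)
  expect_lt(cmp(V[1:8, 7], ref7), 1e-8)
  expect_error(dpssTapers(16, nw = 4, k = 8), "exceeds")
})

test_that("multitaper PSD localizes tones and constants", {
  # single concentrated taper: exact-bin peaks for any phase
  for (ph in c(0, pi / 4, pi / 2)) {
    x <- cos(2 * pi * (8 / 64) * (0:63) + ph)
    ps <- multitaperPSD(x, dt = 1, k = 1, nfft = 64)
    expect_identical(which.max(ps@psd) - 1L, 8L)
  }
  psDC <- multitaperPSD(rep(3.3, 32), dt = 1, k = 1)
  expect_identical(which.max(psDC@psd), 1L)

  # full 7-taper average: peak within the design bandwidth (nw bins)
  x <- sin(2 * pi * (8 / 64) * (0:63))
  ps7 <- multitaperPSD(x, dt = 1, nfft = 64)
  expect_lte(abs(which.max(ps7@psd) - 1L - 8L), 4L)

  expect_error(multitaperPSD(rep(1, 5), dt = 1), "too short")
  expect_error(multitaperPSD(c(1:15, NA), dt = 1), "non-finite")
})

test_that("PSD is non-negative and reduces to the periodogram under a flat taper", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(9:40, 1)
    ps <- multitaperPSD(rnorm(n, sd = runif(1, 0.1, 10)), dt = runif(1, 1, 30))
    expect_true(all(ps@psd >= 0))
    expect_true(all(diff(ps@frequencies) > 0))
    expect_length(ps@psd, 2^ceiling(log2(n)) / 2 + 1)
  }
  x <- rnorm(32)
  flat <- matrix(1 / sqrt(32), 32, 1)
  ps <- multitaperPSD(x, dt = 2, nfft = 32, tapers = flat)
  pg <- 2 * (Mod(fft(x))[1:17])^2 / 32   # dt/N |FFT|^2, one-sided
  pg[2:16] <- 2 * pg[2:16]
  expect_equal(ps@psd, pg, tolerance = 1e-10)
})

test_that("one-sided total power tracks the variance of white noise", {
  set.seed(10)
  ratio <- replicate(400, {
    x <- rnorm(64)
    ps <- multitaperPSD(x, dt = 1, nfft = 64)
    c(sum(ps@psd * ps@frequencies[2]), var(x))
  })
  expect_lt(abs(mean(ratio[1, ]) / mean(ratio[2, ]) - 1), 0.05)
})

test_that("feature assembly has the 7T + 7F layout in fixed channel order", {
  for (T in c(10, 19, 33)) {
    g <- runif(T) + 1; c <- runif(T) + 1; p <- runif(T) + 1
    nfft <- 2^ceiling(log2(T))
    fv <- assembleFeatures(g, c, p, dt = 15)
    expect_identical(length(fv), as.integer(7 * T + 7 * (nfft / 2 + 1)))
    u <- flattenFeatures(fv)
    expect_length(u, 7 * T + 7 * (nfft / 2 + 1))
    # temporal block leads, in G, C, P, GC, GP, CP, GCP order
    expect_equal(u[1:T], g)
    expect_equal(u[(3 * T + 1):(4 * T)], g * c)
  }
  # explicit nfft: T=10, nfft=16 gives F=9, total 133
  fv <- assembleFeatures(runif(10), runif(10), runif(10), dt = 15,
                         psd = psdSettings(nfft = 16))
  expect_identical(length(fv), 133L)

  z <- rep(0, 12)
  expect_true(all(flattenFeatures(assembleFeatures(z, z, z, dt = 15)) == 0))
  expect_error(assembleFeatures(c(NA, runif(9)), runif(10), runif(10),
                                dt = 15), "impute")
})
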