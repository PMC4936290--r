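# Small in-code fixtures shared across test files.

# A tiny complete study: deterministic curves, VAS present.
tinyStudy <- function(nSubjects = 2, times = seq(0, 120, by = 30),
                      name = "tiny") {
  T <- length(times)
  base <- outer(sin(times / 40) + 2, seq_len(nSubjects))  # positive, varied
  vas <- lapply(1:4, function(k) {
    v <- outer(50 + 30 * sin(times / 50 + k), rep(1, nSubjects))
    pmin(pmax(v, 0), 100)
  })
  names(vas) <- c("desire", "hunger", "fullness", "satiety")
  satietyStudy(times, glp1 = base, cck = 0.5 * base, pyy = 10 * base,
               vas = vas, name = name)
}

# Cohort of gamma-shaped GLP-1 curves with exact linear relations
# C = 0.5 G, P = 2 G + 5 (known-functional-relation oracle for the imputer).
linearRelationCurves <- function(n = 60, times = seq(0, 270, by = 15),
                                 seed = 99) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    base <- 8 * exp(rnorm(1, 0, 0.10))
    A <- 12 * exp(rnorm(1, 0, 0.15))
    tp <- 45 * exp(rnorm(1, 0, 0.10))
    z <- times / tp
    base + A * ifelse(z <= 0, 0, z^2 * exp(2 * (1 - z)))
  }))
}

linearRelationStudy <- function(curves, idx, times = seq(0, 270, by = 15)) {
  g <- do.call(cbind, curves[idx])
  satietyStudy(times, glp1 = g, cck = 0.5 * g, pyy = 2 * g + 5,
               name = "linear-relation")
}

# Wrap a single VAS series (same curve in all four channels) as a
# one-subject study, for Pearson-formula tests on evaluateVas().
vasOnlyStudy <- function(v, times = seq(0, by = 15,
                                        length.out = length(v)),
                         name = "vas") {
  T <- length(v)
  vas <- lapply(1:4, function(k) matrix(v, T, 1))
  names(vas) <- c("desire", "hunger", "fullness", "satiety")
  satietyStudy(times, glp1 = matrix(1 + seq_len(T), T, 1), vas = vas,
               name = name)
}

# Textbook Pearson r by explicit summation (independent oracle).
pearsonBySummation <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
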