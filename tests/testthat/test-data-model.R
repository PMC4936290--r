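test_that("study construction enforces the domain invariants", {
  tg <- seq(0, 90, by = 30)
  g <- matrix(2, 4, 1)
  expect_s4_class(satietyStudy(tg, glp1 = g), "SatietyStudy")
  expect_error(satietyStudy(c(0, 30, 30, 60), glp1 = g), "increasing")
  expect_error(satietyStudy(c(0, 30, 60), glp1 = matrix(2, 3, 1)),
               "at least 4")
  expect_error(satietyStudy(tg, glp1 = -g), "non-negative")
  bad <- lapply(setNames(1:4, c("desire", "hunger", "fullness", "satiety")),
                function(k) matrix(101, 4, 1))
  expect_error(satietyStudy(tg, glp1 = g, vas = bad), "\\[0, 100\\]")
  expect_error(satietyStudy(tg), "at least one hormone")
})

test_that("write/read round trip is value-identical and availability-aware", {
  st <- tinyStudy(nSubjects = 3, times = c(0, 17.5, 40, 90, 133))
  # drop CCK to exercise the unavailable path
  st <- maskHormones(st, keep = c("GLP1", "PYY"))
  path <- file.path(withr::local_tempdir(), "study.csv")
  writeStudy(st, path)
  raw <- read.csv(path)
  expect_false(any(raw$variable == "CCK"))
  back <- readStudy(path)
  expect_identical(timeGrid(back), timeGrid(st))
  for (a in assayNames(st))
    expect_identical(unname(assay(back, a)), unname(assay(st, a)),
                     label = a)
  expect_identical(unname(hormoneAvailable(back)),
                   unname(hormoneAvailable(st)))
  expect_identical(studyName(back), studyName(st))

  # a VAS-free study emits no VAS rows
  hOnly <- satietyStudy(timeGrid(st), glp1 = hormoneMatrix(st, "GLP1"),
                        name = "hormones-only")
  writeStudy(hOnly, path)
  expect_false(any(grepl("^VAS", read.csv(path)$variable)))
  # row count = n_times x n_values per present channel
  expect_equal(nrow(read.csv(path)), nrow(hOnly) * ncol(hOnly))
})

test_that("malformed long-format input is rejected with clear errors", {
  dir <- withr::local_tempdir()
  base <- data.frame(study = "s", subject = "S1",
                     time_min = c(0, 30, 60, 90), variable = "GLP1",
                     value = c(1, 2, 3, 4))
  writeBad <- function(d, drop = NULL) {
    p <- file.path(dir, "bad.csv")
    if (!is.null(drop)) d <- d[setdiff(names(d), drop)]
    write.csv(d, p, row.names = FALSE)
    p
  }
  expect_error(readStudy(writeBad(base, drop = "variable")),
               "missing required column")
  expect_error(readStudy(writeBad(transform(base, time_min = time_min - 10))),
               "negative time")
  vas <- transform(base, variable = "VAS_H", value = c(10, 50, 101, 20))
  expect_error(readStudy(writeBad(rbind(base, vas))), "VAS out of range")
  expect_error(readStudy(writeBad(rbind(base, base[2, ]))), "duplicate")
  expect_error(readStudy(writeBad(transform(base, variable = "GHRELIN"))),
               "unknown variable")
})

test_that("resampling interpolates linearly and is exact on knots", {
  st <- satietyStudy(c(0, 60, 120, 180),
                     glp1 = matrix(c(10, 20, 10, 40), 4, 1), name = "r")
  mid <- resampleStudy(st, c(0, 30, 60, 120))
  expect_equal(unname(hormoneMatrix(mid, "GLP1")[2, 1]), 15)  # linear midpoint
  expect_identical(resampleStudy(st, timeGrid(st)), st) # identity case
  expect_error(resampleStudy(st, c(0, 60, 120, 200)), "outside")

  # random piecewise-linear truth: exact at knots, exact everywhere for
  # the implied piecewise-linear interpolant
  knots <- c(0, 20, 45, 80, 130, 200)
  set.seed(3)
  y <- runif(length(knots), 0, 50)
  truth <- satietyStudy(knots, glp1 = matrix(y, ncol = 1), name = "pl")
  dense <- sort(unique(c(knots, seq(0, 200, by = 7))))
  rs <- resampleStudy(truth, dense)
  expect_equal(hormoneMatrix(rs, "GLP1")[match(knots, dense), 1], y,
               tolerance = 0)
  expect_equal(hormoneMatrix(rs, "GLP1")[, 1],
               approx(knots, y, xout = dense)$y)

  # affine series are exact at every resampled point
  aff <- satietyStudy(knots, glp1 = matrix(3 + 0.25 * knots, ncol = 1),
                      name = "affine")
  rs2 <- resampleStudy(aff, dense)
  expect_equal(hormoneMatrix(rs2, "GLP1")[, 1], 3 + 0.25 * dense,
               tolerance = 1e-12)
})

test_that("subject averaging matches explicit summation and respects availability", {
  tg <- seq(0, 90, by = 30)
  two <- satietyStudy(tg, glp1 = cbind(c(1, 3, 1, 3), c(3, 5, 3, 5)),
                      name = "two")
  expect_equal(hormoneMatrix(averageSubjects(two), "GLP1")[, 1],
               c(2, 4, 2, 4))

  one <- tinyStudy(nSubjects = 1)
  expect_equal(assays(averageSubjects(one)), assays(one),
               ignore_attr = TRUE)

  # 50 simulated subjects vs an independent summation loop
  sim <- simulateStudy(simulationConfig(nSubjects = 50, seed = 12))$study
  m <- averageSubjects(sim)
  for (a in assayNames(sim)) {
    byLoop <- numeric(nrow(sim))
    for (i in seq_len(nrow(sim))) {
      s <- 0
      for (j in seq_len(ncol(sim))) s <- s + assay(sim, a)[i, j]
      byLoop[i] <- s / ncol(sim)
    }
    expect_equal(unname(assay(m, a)[, 1]), byLoop, tolerance = 1e-12,
                 label = a)
  }

  # a channel available for a subset is averaged over that subset only
  g <- cbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  cck <- cbind(rep(NA_real_, 4), c(2, 2, 2, 2))
  mixed <- satietyStudy(tg, glp1 = g, cck = cck, name = "mixed")
  expect_equal(hormoneMatrix(averageSubjects(mixed), "CCK")[, 1],
               rep(2, 4))
  expect_error(averageSubjects(mixed[, 0]))
})
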