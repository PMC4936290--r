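#' Train the VAS prediction network
#'
#' One training sample per subject per study: the whole-curve feature
#' vector `U = [I(t), M(t), I(w), M(w)]` in, the four concatenated VAS
#' curves (scaled from their fixed 0-100 range) out. Every training
#' subject must have all three hormones and all four VAS curves; studies
#' are resampled to the first study's grid if needed.
#'
#' @param studies a [SatietyStudy-class] or list of them.
#' @param config a [trainingConfig()] (two hidden layers of 10 by
#'   default; with cohort-sized training sets, early stopping is the
#'   regularizer that matters).
#' @param psd spectral settings from [psdSettings()].
#' @return A [VasModel-class].
#' @export
trainVasModel <- function(studies, config = trainingConfig(),
                          psd = psdSettings()) {
  if (is(studies, "SatietyStudy")) studies <- list(studies)
  grid <- timeGrid(studies[[1L]])
  s <- vasTrainingSamples(studies, grid, psd)
  X <- s$X; Y <- s$Y
  scIn <- fitScaling(X)
  scOut <- new("ScalingSpec", min = rep(0, ncol(Y)), max = rep(100, ncol(Y)),
               lo = 0.1, hi = 0.9, shared = FALSE)   # VAS scale is known
  net <- nnTrain(applyScaling(scIn, X), applyScaling(scOut, Y), config)
  new("VasModel", net = net, scalingIn = scIn, scalingOut = scOut,
      grid = grid, psd = psd)
}

# One (feature, target) sample per subject per study, whole curves each
vasTrainingSamples <- function(studies, grid, psd) {
  dt <- grid[2L] - grid[1L]
  X <- list(); Y <- list()
  for (st in studies) {
    st <- resampleStudy(st, grid)
    if (!all(hormoneAvailable(st)))
      stop("training subjects must have all three hormones (study ",
           studyName(st), ")")
    if (!hasVAS(st))
      stop("training subjects must have VAS curves (study ",
           studyName(st), ")")
    for (j in seq_len(ncol(st))) {
      fv <- assembleFeatures(assay(st, "GLP1")[, j], assay(st, "CCK")[, j],
                             assay(st, "PYY")[, j], dt = dt, psd = psd)
      X[[length(X) + 1L]] <- flattenFeatures(fv)
      Y[[length(Y) + 1L]] <- c(vasMatrix(st, "desire")[, j],
                               vasMatrix(st, "hunger")[, j],
                               vasMatrix(st, "fullness")[, j],
                               vasMatrix(st, "satiety")[, j])
    }
  }
  list(X = do.call(rbind, X), Y = do.call(rbind, Y))
}

#' Predict VAS curves for a study
#'
#' Per subject: extend hormone curves that stop short of the model grid
#' (closed-loop, via the per-channel extender models), impute any missing
#' hormone channel, assemble features, run the network, and de-scale to
#' the 0-100 VAS range (clamped at the scaling bounds). Subjects already
#' complete and on the model grid pass through untouched (empty
#' provenance).
#'
#' @param model a [VasModel-class].
#' @param study a [SatietyStudy-class]; every subject needs >= 1 hormone.
#' @param imputer a [HormoneImputer-class], required when any hormone is
#'   missing.
#' @param extenders named list of [NarxModel-class], required when the
#'   study grid stops before the model grid.
#' @return The study on the model grid with the four VAS assays replaced
#'   by predictions; imputation/extension steps recorded in
#'   `metadata()$provenance`.
#' @export
predictVas <- function(model, study, imputer = NULL, extenders = NULL) {
  grid <- model@grid
  dt <- grid[2L] - grid[1L]
  if (max(timeGrid(study)) < max(grid)) {
    if (is.null(extenders))
      stop("study grid stops at ", max(timeGrid(study)), " min but the ",
           "model needs ", max(grid), " min; supply extender models")
    study <- resampleStudy(study, grid[grid <= max(timeGrid(study))])
    study <- extendStudy(extenders, study, grid)
  } else {
    study <- resampleStudy(study, grid)
  }
  if (!all(hormoneAvailable(study))) {
    if (is.null(imputer))
      stop("missing hormone channels; supply an imputer model")
    study <- imputeStudy(imputer, study)
  }
  T <- length(grid)
  pred <- lapply(setNames(VAS_TYPES, VAS_TYPES), function(v)
    matrix(NA_real_, T, ncol(study)))
  for (j in seq_len(ncol(study))) {
    fv <- assembleFeatures(assay(study, "GLP1")[, j], assay(study, "CCK")[, j],
                           assay(study, "PYY")[, j], dt = dt, psd = model@psd)
    u <- applyScaling(model@scalingIn, matrix(flattenFeatures(fv), nrow = 1L),
                      clamp = TRUE)
    y <- invertScaling(model@scalingOut, nnForward(model@net, u),
                       clamp = TRUE)
    for (i in seq_along(VAS_TYPES))
      pred[[VAS_TYPES[i]]][, j] <- y[1L, ((i - 1L) * T + 1L):(i * T)]
  }
  out <- satietyStudy(grid, glp1 = assay(study, "GLP1"),
                      cck = assay(study, "CCK"), pyy = assay(study, "PYY"),
                      vas = pred, name = studyName(study),
                      route = metadata(study)$route,
                      window = metadata(study)$window,
                      subjects = colnames(study),
                      units = unlist(metadata(study)$units))
  metadata(out)$provenance <- metadata(study)$provenance
  out
}

#' Compare predicted and measured VAS curves
#'
#' Averages both studies over subjects, then computes the Pearson
#' correlation over time points between the averaged predicted and
#' measured curve for each VAS type — the cohort-level evaluation
#' statistic. A zero-variance averaged measured or predicted curve yields
#' `NA` for that type (undefined, never coerced to 0).
#'
#' @param predicted,measured [SatietyStudy-class] objects on the same grid
#'   with the same subjects.
#' @return An [EvaluationReport-class].
#' @export
evaluateVas <- function(predicted, measured) {
  if (!identical(colnames(predicted), colnames(measured)))
    stop("subject sets differ")
  if (!isTRUE(all.equal(timeGrid(predicted), timeGrid(measured))))
    stop("time grids differ")
  pm <- averageSubjects(predicted)
  mm <- averageSubjects(measured)
  r <- vapply(VAS_TYPES, function(v) {
    a <- vasMatrix(pm, v)[, 1L]; b <- vasMatrix(mm, v)[, 1L]
    if (anyNA(a) || anyNA(b)) return(NA_real_)
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1L))
  new("EvaluationReport", r = r, average = mean(r),
      nSubjects = ncol(measured), study = studyName(measured))
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport for \"", object@study, "\" (", object@nSubjects,
      " subjects)\n", sep = "")
  cat(paste(sprintf("  %-8s r = %s", names(object@r),
                    formatC(object@r, digits = 3, format = "f")),
            collapse = "\n"), "\n")
  cat(sprintf("  average  r = %s\n",
              formatC(object@average, digits = 3, format = "f")))
})

#' @describeIn evaluateVas correlations as a one-row data.frame.
#' @param report an `EvaluationReport`.
#' @export
reportAsFrame <- function(report) {
  data.frame(study = report@study, n = report@nSubjects,
             t(report@r), average = report@average)
}

# Table-style ordering of the 7 non-empty hormone subsets
ABLATION_COMBOS <- list(
  a = "GLP1", b = c("GLP1", "CCK", "PYY"), c = c("GLP1", "CCK"),
  d = c("GLP1", "PYY"), e = c("CCK", "PYY"), f = "CCK", g = "PYY")

#' Hormone-ablation evaluation
#'
#' Rebuilds the test set for each of the 7 non-empty subsets of
#' {GLP-1, CCK, PYY}: masks the complement, imputes the missing channels,
#' predicts VAS with the same trained model, and evaluates against the
#' measured VAS. Measures how much each hormone combination carries the
#' VAS signal.
#'
#' @param model a trained [VasModel-class].
#' @param imputer a trained [HormoneImputer-class].
#' @param testStudy a [SatietyStudy-class] with all three hormones and
#'   measured VAS.
#' @param extenders optional extender models passed to [predictVas()].
#' @return A 7-row data.frame (rows labelled a-g): hormone availability
#'   flags, per-VAS r and their average.
#' @export
hormoneAblation <- function(model, imputer, testStudy, extenders = NULL) {
  if (!all(hormoneAvailable(testStudy)))
    stop("ablation needs a test study with all three hormones")
  rows <- lapply(names(ABLATION_COMBOS), function(lab) {
    keep <- ABLATION_COMBOS[[lab]]
    masked <- maskHormones(testStudy, keep)
    pred <- predictVas(model, masked, imputer = imputer,
                       extenders = extenders)
    rep <- evaluateVas(pred, resampleStudy(testStudy, model@grid))
    data.frame(combo = lab, GLP1 = "GLP1" %in% keep, CCK = "CCK" %in% keep,
               PYY = "PYY" %in% keep, t(rep@r), average = rep@average)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$combo
  out
}
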