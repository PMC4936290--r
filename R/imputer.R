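#' Train the missing-hormone imputation network
#'
#' One shared two-hidden-layer network mapping any single hormone curve
#' (length T) to the complete `[G(t), C(t), P(t)]` curve set (length 3T).
#' Following the one-in/three-out protocol, every complete hormone set
#' contributes exactly three training presentations — its GLP-1, its CCK
#' and its PYY curve each paired with the full triple as target — so a
#' cohort of `n` complete sets yields `3n` training pairs pooled into one
#' fit. The input is identity-free: no tag says which hormone is shown,
#' and the input scaling is a single range shared across all three
#' hormones so magnitude cannot leak identity either.
#'
#' @param studies a [SatietyStudy-class] or list of them; every subject
#'   must have all three hormones available on a shared grid.
#' @param config a [trainingConfig()]; the default two hidden layers of 10
#'   apply.
#' @return A [HormoneImputer-class].
#' @export
trainImputer <- function(studies, config = trainingConfig()) {
  if (is(studies, "SatietyStudy")) studies <- list(studies)
  tg <- timeGrid(studies[[1L]])
  sets <- list()
  for (st in studies) {
    if (!isTRUE(all.equal(timeGrid(st), tg))) stop("grid mismatch across studies")
    av <- hormoneAvailable(st)
    if (!all(av)) stop("every training subject needs all three hormones")
    for (j in seq_len(ncol(st)))
      sets[[length(sets) + 1L]] <- list(G = assay(st, "GLP1")[, j],
                                        C = assay(st, "CCK")[, j],
                                        P = assay(st, "PYY")[, j])
  }
  pairs <- imputerPairs(sets)
  scIn <- fitScaling(pairs$X, shared = TRUE)
  scOut <- fitScaling(pairs$Y)
  net <- nnTrain(applyScaling(scIn, pairs$X), applyScaling(scOut, pairs$Y),
                 config)
  new("HormoneImputer", net = net, scalingIn = scIn, scalingOut = scOut,
      gridLength = length(tg))
}

# Three (input, target) presentations per complete set: G->GCP, C->GCP, P->GCP
imputerPairs <- function(sets) {
  X <- do.call(rbind, lapply(sets, function(s) rbind(s$G, s$C, s$P)))
  Y <- do.call(rbind, lapply(sets, function(s) {
    tgt <- c(s$G, s$C, s$P)
    rbind(tgt, tgt, tgt)
  }))
  list(X = unname(X), Y = unname(Y))
}

#' Predict the full hormone curve set from one measured curve
#'
#' Runs the trained imputation network on a single hormone curve and
#' returns the predicted GLP-1, CCK and PYY curves, de-scaled and clamped
#' to non-negative concentrations.
#'
#' @param model a [HormoneImputer-class].
#' @param x one hormone curve on the model's grid (length T).
#' @return A 3-row matrix (`GLP1`, `CCK`, `PYY`) of length-T predictions.
#' @export
imputeHormones <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model@gridLength)
    stop("curve length ", length(x), " does not match model grid length ",
         model@gridLength)
  u <- applyScaling(model@scalingIn, matrix(x, nrow = 1L), clamp = TRUE)
  y <- invertScaling(model@scalingOut, nnForward(model@net, u))
  y <- pmax(y, 0)
  T <- model@gridLength
  rbind(GLP1 = y[1, 1:T], CCK = y[1, (T + 1):(2 * T)],
        PYY = y[1, (2 * T + 1):(3 * T)])
}

#' Fill missing hormone channels of a study by imputation
#'
#' For each subject, every missing hormone is predicted from each of the
#' subject's measured hormone curves and the predictions are averaged
#' (the symmetric choice when two inputs are available). Measured
#' channels are never overwritten. Imputed channels are recorded in the
#' study's provenance metadata.
#'
#' @param model a [HormoneImputer-class].
#' @param study a [SatietyStudy-class] on the model's grid, every subject
#'   with >= 1 hormone.
#' @return The study with all three hormones available.
#' @export
imputeStudy <- function(model, study) {
  if (nrow(study) != model@gridLength)
    stop("study grid length does not match the imputer")
  av <- hormoneAvailable(study)
  if (all(av)) return(study)
  a <- list(GLP1 = assay(study, "GLP1"), CCK = assay(study, "CCK"),
            PYY = assay(study, "PYY"))
  filled <- list()
  for (j in seq_len(ncol(study))) {
    have <- HORMONES[av[, j]]
    need <- HORMONES[!av[, j]]
    if (!length(have)) stop("subject ", colnames(study)[j], " has no hormones")
    if (!length(need)) next
    preds <- lapply(have, function(h) imputeHormones(model, a[[h]][, j]))
    for (h in need) {
      a[[h]][, j] <- rowMeans(vapply(preds, function(p) p[h, ],
                                     numeric(nrow(study))))
      filled[[length(filled) + 1L]] <-
        list(subject = colnames(study)[j], channel = h, from = have)
    }
  }
  out <- satietyStudy(timeGrid(study), glp1 = a$GLP1, cck = a$CCK,
                      pyy = a$PYY,
                      vas = if (hasVAS(study))
                        setNames(lapply(VAS_TYPES, vasMatrix, x = study),
                                 VAS_TYPES),
                      name = studyName(study), route = metadata(study)$route,
                      window = metadata(study)$window,
                      subjects = colnames(study),
                      units = unlist(metadata(study)$units))
  metadata(out)$provenance <- c(metadata(study)$provenance,
                                list(imputed = filled))
  out
}

setMethod("show", "HormoneImputer", function(object) {
  cat(sprintf("HormoneImputer: %d-point grid, 1 curve in -> 3 curves out\n",
              object@gridLength))
  show(object@net)
})
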