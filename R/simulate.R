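#' Configuration of the synthetic satiety-study generator
#'
#' Defines the statistical structure the analysis assumes: gamma-shaped
#' postprandial hormone responses with lognormal subject-level variation
#' and Gaussian measurement noise, and VAS curves produced from the
#' noiseless hormones by a known log-sigmoid ground-truth mapping with one
#' triple-interaction term. Defaults emulate a 15-subject crossover arm
#' sampled every 15 min over 0-270 min, with hormone magnitudes on the
#' scales of their usual units (GLP-1 and CCK in pmol/l, order 1-20; PYY
#' in pg/ml, order 50-200).
#'
#' @param nSubjects subjects per study (>= 2).
#' @param times sampling grid, minutes.
#' @param mealOnset meal/infusion start, minutes.
#' @param hormones per-hormone response parameters: `baseline` (resting
#'   concentration), `amplitude` (peak response above baseline),
#'   `tp` (time from onset to peak, min), `shape` (gamma shape of the
#'   rise-decay), `noiseSd` (measurement noise sd, concentration units).
#' @param subjectSdBaseline,subjectSdResponse,subjectSdTiming sdlog of the
#'   lognormal subject effects multiplying baseline, response amplitude
#'   and time-to-peak. Effects are drawn independently per subject and
#'   per hormone, so each hormone carries partly subject-specific
#'   information (as real satiety hormones do) and removing a channel
#'   genuinely discards signal.
#' @param vasWeights ground-truth mapping weights for the two satiating
#'   scores; each is `c(b0, G, C, P, GCP)` applied to reference-range
#'   normalised noiseless hormones inside `100 * logsig(.)`. Hunger and
#'   desire are the complements of satiety and fullness.
#' @param vasNoiseSd measurement noise sd on observed VAS points.
#' @param foodEffect multiplier on all response amplitudes (food-type
#'   contrast).
#' @param seed explicit RNG seed; identical config + seed is bit-identical.
#' @param name,route study label and administration route.
#' @return Config list for [simulateStudy()].
#' @export
simulationConfig <- function(
    nSubjects = 15, times = seq(0, 270, by = 15), mealOnset = 0,
    hormones = list(
      GLP1 = list(baseline = 8,  amplitude = 12, tp = 45, shape = 2, noiseSd = 0.6),
      CCK  = list(baseline = 2,  amplitude = 4,  tp = 30, shape = 2, noiseSd = 0.2),
      PYY  = list(baseline = 90, amplitude = 60, tp = 60, shape = 2, noiseSd = 4)),
    subjectSdBaseline = 0.1, subjectSdResponse = 0.2, subjectSdTiming = 0.1,
    vasWeights = list(
      satiety  = c(b0 = -2,   G = 2,   C = 1,   P = 1.5, GCP = 1.5),
      fullness = c(b0 = -1.8, G = 1.5, C = 1.5, P = 1,   GCP = 1)),
    vasNoiseSd = 3, foodEffect = 1, seed = 1, name = "synthetic",
    route = "oral") {
  stopifnot(nSubjects >= 2, length(times) >= 4, all(diff(times) > 0),
            vasNoiseSd >= 0, foodEffect > 0, length(seed) == 1L)
  for (h in hormones)
    stopifnot(h$baseline >= 0, h$amplitude >= 0, h$noiseSd >= 0, h$tp > 0)
  list(nSubjects = as.integer(nSubjects), times = as.numeric(times),
       mealOnset = mealOnset, hormones = hormones,
       subjectSdBaseline = subjectSdBaseline,
       subjectSdResponse = subjectSdResponse,
       subjectSdTiming = subjectSdTiming, vasWeights = vasWeights,
       vasNoiseSd = vasNoiseSd, foodEffect = foodEffect,
       seed = as.integer(seed), name = name, route = route)
}

# Gamma-shaped postprandial response, 0 before onset, peak 1 at onset + tp
gammaResponse <- function(t, onset, tp, shape = 2) {
  z <- (t - onset) / tp
  ifelse(z <= 0, 0, z^shape * exp(shape * (1 - z)))
}

#' Simulate one synthetic satiety study with known ground truth
#'
#' Hormone `h` of subject `i` is
#' `baseline_h * m_ih + amplitude_h * foodEffect * f_ih * g(t; tp_h * s_ih)
#' + noise`, clamped at zero, with `g` the gamma-shaped response and
#' `m_ih`, `f_ih`, `s_ih` lognormal subject-by-hormone effects on
#' baseline, amplitude and timing. The ground-truth satiating scores are
#' `100 * logsig(b0 + sum(beta_h * hnorm) + beta_GCP * Gn*Cn*Pn)` on
#' noiseless hormones normalised by their population reference range
#' (`(h - baseline) / amplitude`); hunger and desire are `100 -` satiety
#' and fullness. Observed VAS adds Gaussian noise and clamps to [0, 100].
#'
#' @param config a [simulationConfig()].
#' @return `list(study = SatietyStudy, truth = list(...))`; `truth` holds
#'   the noiseless hormone and VAS matrices, the subject effects and the
#'   generating weights.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  withLocalSeed(config$seed, {
    tg <- config$times
    n <- config$nSubjects
    draw <- function(sd) matrix(exp(rnorm(n * 3L, 0, sd)), n, 3L,
                                dimnames = list(NULL, HORMONES))
    m <- draw(config$subjectSdBaseline)   # baseline effects
    f <- draw(config$subjectSdResponse)   # amplitude effects
    s <- draw(config$subjectSdTiming)     # time-to-peak effects
    hTrue <- hObs <- list()
    for (h in HORMONES) {
      p <- config$hormones[[h]]
      truth <- vapply(seq_len(n), function(i)
        p$baseline * m[i, h] +
          p$amplitude * config$foodEffect * f[i, h] *
          gammaResponse(tg, config$mealOnset, p$tp * s[i, h], p$shape),
        numeric(length(tg)))
      hTrue[[h]] <- truth
      hObs[[h]] <- pmax(truth + matrix(rnorm(length(tg) * n, 0, p$noiseSd),
                                       length(tg), n), 0)
    }
    nrm <- lapply(HORMONES, function(h)
      (hTrue[[h]] - config$hormones[[h]]$baseline) /
        config$hormones[[h]]$amplitude)
    names(nrm) <- HORMONES
    scoreOf <- function(w)
      100 * logsig(w[["b0"]] + w[["G"]] * nrm$GLP1 + w[["C"]] * nrm$CCK +
                     w[["P"]] * nrm$PYY +
                     w[["GCP"]] * nrm$GLP1 * nrm$CCK * nrm$PYY)
    vTrue <- list(satiety = scoreOf(config$vasWeights$satiety),
                  fullness = scoreOf(config$vasWeights$fullness))
    vTrue$hunger <- 100 - vTrue$satiety
    vTrue$desire <- 100 - vTrue$fullness
    vObs <- lapply(vTrue[VAS_TYPES], function(v)
      pmin(pmax(v + matrix(rnorm(length(v), 0, config$vasNoiseSd),
                           nrow(v), ncol(v)), 0), 100))
    study <- satietyStudy(tg, glp1 = hObs$GLP1, cck = hObs$CCK,
                          pyy = hObs$PYY, vas = vObs, name = config$name,
                          route = config$route,
                          window = c(config$mealOnset, config$mealOnset))
    list(study = study,
         truth = list(hormones = hTrue, vas = vTrue[VAS_TYPES],
                      subjectBaseline = m, subjectResponse = f,
                      subjectTiming = s, weights = config$vasWeights,
                      config = config))
  })
}

#' Build a study matching a canonical availability scenario
#'
#' `"complete"`: all three hormones and VAS (full-training-set role).
#' `"missing_cck"`: CCK dropped for every subject (two-hormone test-set
#' role). `"glp1_only_short"`: only GLP-1, truncated to the first
#' `floor(2/3 * T)` grid points (single-hormone short-sampling test-set
#' role).
#'
#' @param name scenario name.
#' @param config a [simulationConfig()].
#' @return A [SatietyStudy-class].
#' @export
makeScenario <- function(name = c("complete", "missing_cck",
                                  "glp1_only_short"),
                         config = simulationConfig()) {
  name <- match.arg(name)
  full <- simulateStudy(config)$study
  switch(name,
    complete = full,
    missing_cck = maskHormones(full, keep = c("GLP1", "PYY")),
    glp1_only_short = {
      keepT <- seq_len(floor(2 / 3 * nrow(full)))
      short <- resampleStudy(full, timeGrid(full)[keepT])
      maskHormones(short, keep = "GLP1")
    })
}

#' Drop hormone channels from a study
#'
#' Marks all but `keep` unavailable (all-`NA`), as when building hormone
#' ablation test sets.
#'
#' @param x a [SatietyStudy-class].
#' @param keep hormone names to retain.
#' @return The masked study.
#' @export
maskHormones <- function(x, keep) {
  keep <- match.arg(keep, HORMONES, several.ok = TRUE)
  a <- lapply(setNames(HORMONES, HORMONES), function(h)
    if (h %in% keep) assay(x, h) else NULL)
  vas <- if (hasVAS(x))
    setNames(lapply(VAS_TYPES, vasMatrix, x = x), VAS_TYPES)
  satietyStudy(timeGrid(x), glp1 = a$GLP1, cck = a$CCK, pyy = a$PYY,
               vas = vas, name = studyName(x), route = metadata(x)$route,
               window = metadata(x)$window, subjects = colnames(x),
               units = unlist(metadata(x)$units))
}

#' @describeIn simulationConfig weights making satiety depend on GLP-1
#'   alone (used to probe hormone-ablation orderings).
#' @export
gDominantWeights <- function() {
  list(satiety  = c(b0 = -2,   G = 3,   C = 0, P = 0, GCP = 0),
       fullness = c(b0 = -1.8, G = 2.5, C = 0, P = 0, GCP = 0))
}
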