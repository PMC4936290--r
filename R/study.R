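#' Construct a SatietyStudy
#'
#' Assembles hormone and VAS matrices on a shared time grid into a
#' [SatietyStudy-class]. Matrices are time x subject; pass `NULL` for a
#' hormone nobody measured and `NA` columns for per-subject gaps. VAS
#' matrices may be omitted (e.g. a hormone-only test arm before
#' prediction).
#'
#' @param times strictly increasing sampling times, minutes since first
#'   sample; length >= 4.
#' @param glp1,cck,pyy hormone concentration matrices (`NULL` = channel
#'   unavailable). GLP-1 and CCK in pmol/l, PYY in pg/ml.
#' @param vas named list with elements `desire`, `hunger`, `fullness`,
#'   `satiety` (each time x subject, 0-100), or `NULL`.
#' @param name non-empty study label (food/infusion arm).
#' @param route one of `"oral"`, `"gastric"`, `"ileal"`.
#' @param window meal/infusion window in minutes, length-2 numeric.
#' @param subjects subject identifiers; defaults to `S1..Sn`.
#' @param units concentration units carried as metadata, never converted.
#' @return A validated [SatietyStudy-class].
#' @examples
#' tg <- seq(0, 90, by = 30)
#' g <- matrix(rep(c(5, 15, 10, 6), 2), ncol = 2)
#' satietyStudy(tg, glp1 = g, name = "demo")
#' @export
satietyStudy <- function(times, glp1 = NULL, cck = NULL, pyy = NULL,
                         vas = NULL, name = "study", route = "oral",
                         window = c(0, 0), subjects = NULL,
                         units = c(GLP1 = "pmol/l", CCK = "pmol/l",
                                   PYY = "pg/ml")) {
  times <- as.numeric(times)
  given <- Filter(Negate(is.null), list(glp1, cck, pyy, vas[["desire"]]))
  if (!length(given)) stop("at least one hormone channel is required")
  n <- ncol(as.matrix(given[[1L]]))
  if (is.null(subjects)) subjects <- paste0("S", seq_len(n))
  blank <- matrix(NA_real_, length(times), n)
  shape <- function(m) {
    if (is.null(m)) return(blank)
    m <- as.matrix(m)
    if (nrow(m) != length(times) || ncol(m) != n)
      stop("channel matrix must be length(times) x n_subjects")
    m
  }
  a <- list(GLP1 = shape(glp1), CCK = shape(cck), PYY = shape(pyy))
  for (v in VAS_TYPES) a[[VAS_COLUMNS[[v]]]] <- shape(vas[[v]])
  a <- lapply(a, function(m) { dimnames(m) <- list(NULL, subjects); m })
  avail <- matrix(unlist(lapply(HORMONES, function(h)
    colSums(!is.na(a[[h]])) > 0)), nrow = n,
    dimnames = list(NULL, HORMONES))
  cd <- DataFrame(subject = subjects,
                  avail.GLP1 = avail[, "GLP1"], avail.CCK = avail[, "CCK"],
                  avail.PYY = avail[, "PYY"], row.names = subjects)
  route <- match.arg(route, c("oral", "gastric", "ileal"))
  se <- SummarizedExperiment(
    assays = a, rowData = DataFrame(time_min = times), colData = cd,
    metadata = list(name = name, route = route, window = window,
                    units = as.list(units), provenance = list()))
  new("SatietyStudy", se)
}

#' @describeIn satietyStudy sampling times (minutes) of a study.
#' @param x a `SatietyStudy`.
#' @export
timeGrid <- function(x) rowData(x)$time_min

#' @describeIn satietyStudy study label.
#' @export
studyName <- function(x) metadata(x)$name

#' @describeIn satietyStudy 3 x n_subjects logical matrix of per-subject
#'   hormone availability.
#' @export
hormoneAvailable <- function(x) {
  cd <- colData(x)
  m <- rbind(GLP1 = cd$avail.GLP1, CCK = cd$avail.CCK, PYY = cd$avail.PYY)
  colnames(m) <- colnames(x)
  m
}

#' @describeIn satietyStudy `TRUE` when all four VAS assays carry data.
#' @export
hasVAS <- function(x) {
  all(vapply(VAS_COLUMNS, function(v) !all(is.na(assay(x, v))), logical(1L)))
}

#' @describeIn satietyStudy one hormone matrix (time x subject).
#' @param hormone one of `"GLP1"`, `"CCK"`, `"PYY"`.
#' @export
hormoneMatrix <- function(x, hormone) assay(x, match.arg(hormone, HORMONES))

#' @describeIn satietyStudy one VAS matrix (time x subject).
#' @param type one of `"desire"`, `"hunger"`, `"fullness"`, `"satiety"`.
#' @export
vasMatrix <- function(x, type) assay(x, VAS_COLUMNS[[match.arg(type, VAS_TYPES)]])

setMethod("show", "SatietyStudy", function(object) {
  av <- hormoneAvailable(object)
  cat("SatietyStudy \"", studyName(object), "\" (", metadata(object)$route,
      ")\n", sep = "")
  cat(sprintf("  %d subjects, %d time points (%g-%g min)\n", ncol(object),
              nrow(object), min(timeGrid(object)), max(timeGrid(object))))
  cat("  hormones available: ",
      paste(sprintf("%s %d/%d", rownames(av), rowSums(av), ncol(av)),
            collapse = ", "), "\n", sep = "")
  cat("  VAS curves: ", if (hasVAS(object)) "present" else "absent", "\n",
      sep = "")
})

#' Resample a study onto a target time grid
#'
#' Linear interpolation of every channel of every subject onto `target`.
#' Points that coincide with source times are reproduced exactly;
#' extrapolation is refused (extending beyond the measured range is the
#' job of [extendStudy()]).
#'
#' @param x a [SatietyStudy-class].
#' @param target strictly increasing times within the source range.
#' @return The resampled study; availability flags are unchanged.
#' @export
resampleStudy <- function(x, target) {
  target <- as.numeric(target)
  src <- timeGrid(x)
  if (min(target) < min(src) || max(target) > max(src))
    stop("target grid outside source range; use extendStudy() to extrapolate")
  if (length(target) == length(src) && all(target == src)) return(x)
  interp <- function(m) {
    apply(m, 2L, function(y) {
      if (all(is.na(y))) return(rep(NA_real_, length(target)))
      approx(src, y, xout = target, method = "linear")$y
    })
  }
  a <- lapply(assays(x), interp)
  a <- lapply(a, function(m) { colnames(m) <- colnames(x); m })
  se <- SummarizedExperiment(assays = a,
                             rowData = DataFrame(time_min = target),
                             colData = colData(x), metadata = metadata(x))
  new("SatietyStudy", se)
}

#' Average a study over subjects
#'
#' Pointwise arithmetic mean of every channel over the subjects for which
#' that channel is available, yielding a one-subject study labelled
#' `"MEAN"` — the cohort-average curves the evaluation statistic is
#' computed on.
#'
#' @param x a [SatietyStudy-class] with >= 1 subject.
#' @return A one-subject `SatietyStudy`.
#' @export
averageSubjects <- function(x) {
  if (ncol(x) < 1L) stop("empty study")
  for (h in HORMONES)
    if (any(hormoneAvailable(x)[h, ]) && all(is.na(assay(x, h))))
      stop("channel ", h, " flagged available but has no data")
  avg <- function(m) {
    out <- rowMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    matrix(out, ncol = 1L, dimnames = list(NULL, "MEAN"))
  }
  a <- lapply(assays(x), avg)
  av <- hormoneAvailable(x)
  cd <- DataFrame(subject = "MEAN",
                  avail.GLP1 = any(av["GLP1", ]), avail.CCK = any(av["CCK", ]),
                  avail.PYY = any(av["PYY", ]), row.names = "MEAN")
  se <- SummarizedExperiment(assays = a,
                             rowData = DataFrame(time_min = timeGrid(x)),
                             colData = cd, metadata = metadata(x))
  new("SatietyStudy", se)
}

# Canonical uniform grid: step = median source interval rounded to 5 min
canonicalGrid <- function(times) {
  step <- max(5, round(stats::median(diff(times)) / 5) * 5)
  seq(min(times), max(times), by = step)
}
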