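LONG_COLUMNS <- c("study", "subject", "time_min", "variable", "value")
LONG_VARIABLES <- c(HORMONES, unname(VAS_COLUMNS))

sidecarPath <- function(path) sub("\\.csv$", ".yml", path)

#' Read a study from long-format CSV
#'
#' Expects columns `study, subject, time_min, variable, value` with
#' `variable` in `GLP1, CCK, PYY, VAS_D, VAS_H, VAS_F, VAS_S`. Hormones
#' with no rows for a subject are flagged unavailable. If the per-subject
#' sampling times differ, all series are aligned by linear interpolation
#' onto a canonical uniform grid (step = median sampling interval rounded
#' to 5 min) spanning the common time range. A YAML sidecar
#' (`<path>.yml` next to the CSV) supplies study metadata when present.
#'
#' @param path CSV file path.
#' @param study study name to extract when the file holds several.
#' @return A [SatietyStudy-class].
#' @export
readStudy <- function(path, study = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LONG_COLUMNS, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(study)) {
    study <- unique(d$study)
    if (length(study) != 1L)
      stop("file contains several studies (", paste(study, collapse = ", "),
           "); pass `study`")
  }
  d <- d[d$study == study, , drop = FALSE]
  if (!nrow(d)) stop("no rows for study ", study)
  bad <- setdiff(unique(d$variable), LONG_VARIABLES)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  if (any(d$time_min < 0)) stop("negative time")
  isVas <- d$variable %in% VAS_COLUMNS
  if (any(d$value[isVas] < 0 | d$value[isVas] > 100))
    stop("VAS out of range [0, 100]")
  if (anyDuplicated(d[c("subject", "time_min", "variable")]))
    stop("duplicate (subject, time, variable) cell")

  subjects <- unique(d$subject)
  series <- split(d, interaction(d$subject, d$variable, drop = TRUE))
  grids <- lapply(series, function(s) sort(s$time_min))
  same <- all(vapply(grids, function(g) identical(g, grids[[1L]]), logical(1L)))
  tg <- if (same) grids[[1L]] else {
    lo <- max(vapply(grids, min, numeric(1L)))
    hi <- min(vapply(grids, max, numeric(1L)))
    if (hi <= lo) stop("subject time ranges do not overlap")
    canonicalGrid(sort(unique(d$time_min[d$time_min >= lo & d$time_min <= hi])))
  }
  if (length(tg) < 4L) stop("time grid must have at least 4 points")

  pick <- function(variable) {
    m <- matrix(NA_real_, length(tg), length(subjects))
    for (j in seq_along(subjects)) {
      s <- d[d$subject == subjects[j] & d$variable == variable, , drop = FALSE]
      if (!nrow(s)) next
      o <- order(s$time_min)
      m[, j] <- approx(s$time_min[o], s$value[o], xout = tg,
                       method = "linear")$y
    }
    if (all(is.na(m))) NULL else m
  }
  vas <- lapply(VAS_COLUMNS, pick)
  names(vas) <- VAS_TYPES
  if (all(vapply(vas, is.null, logical(1L)))) vas <- NULL

  meta <- list(name = study, route = "oral", window = c(0, 0),
               units = c(GLP1 = "pmol/l", CCK = "pmol/l", PYY = "pg/ml"))
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    y <- yaml::read_yaml(sc)
    for (f in intersect(names(y), c("name", "route", "window", "units")))
      meta[[f]] <- y[[f]]
  }
  satietyStudy(tg, glp1 = pick("GLP1"), cck = pick("CCK"), pyy = pick("PYY"),
               vas = vas, name = meta$name, route = meta$route,
               window = as.numeric(unlist(meta$window)), subjects = subjects,
               units = unlist(meta$units))
}

#' Write a study to long-format CSV (plus YAML metadata sidecar)
#'
#' Emits one row per (subject, time, variable) value; unavailable hormones
#' and `NA` cells emit no rows. Metadata (name, route, infusion window,
#' units) goes to `<path>.yml`.
#'
#' @param x a [SatietyStudy-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeStudy <- function(x, path) {
  validObject(x)
  tg <- timeGrid(x)
  rows <- list()
  for (v in names(assays(x))) {
    m <- assay(x, v)
    for (j in seq_len(ncol(m))) {
      keep <- !is.na(m[, j])
      if (!any(keep)) next
      # %.17g keeps the round trip bit-exact through the text file
      rows[[length(rows) + 1L]] <- data.frame(
        study = studyName(x), subject = colnames(x)[j],
        time_min = sprintf("%.17g", tg[keep]),
        variable = v, value = sprintf("%.17g", m[keep, j]))
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  md <- metadata(x)
  yaml::write_yaml(list(name = md$name, route = md$route,
                        window = as.numeric(md$window), units = md$units),
                   sidecarPath(path))
  invisible(path)
}
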