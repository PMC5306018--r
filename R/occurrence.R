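## Presence-only to presence-absence conversion via the well-surveyed-tetrad
## criterion: a tetrad qualifies to supply inferred absences only if it was
## surveyed at least twice within the study window with at least 50 plant
## species recorded in each counted survey.

#' Simplify occurrence records to tetrad level
#'
#' Records coarser than tetrad precision are discarded; records finer than
#' tetrad precision are re-keyed to their containing tetrad; duplicate
#' (species, tetrad) pairs are collapsed. Records outside the calendar
#' window (endpoints inclusive) are dropped. Records with an unknown
#' precision class are rejected; their count is attached as attribute
#' `rejected` and reported with a warning.
#'
#' @param records data.frame with columns species, tetrad_id, year, precision
#'   (precision one of `"finer"`, `"tetrad"`, `"coarser"`)
#' @param window inclusive year range (default 1950-2014)
#' @return data.frame with columns species, tetrad_id; attributes
#'   `dropped_coarse`, `dropped_window`, `rejected`
#' @export
simplifyRecords <- function(records, window = c(1950, 2014)) {
  stopifnot(all(c("species", "tetrad_id", "year", "precision") %in%
                names(records)))
  known <- records$precision %in% c("finer", "tetrad", "coarser")
  nRejected <- sum(!known)
  if (nRejected > 0)
    warning(nRejected, " record(s) with unknown precision class rejected")
  records <- records[known, , drop = FALSE]
  inWindow <- records$year >= window[1] & records$year <= window[2]
  nWindow <- sum(!inWindow)
  records <- records[inWindow, , drop = FALSE]
  coarse <- records$precision == "coarser"
  nCoarse <- sum(coarse)
  records <- records[!coarse, , drop = FALSE]
  out <- unique(records[, c("species", "tetrad_id")])
  rownames(out) <- NULL
  attr(out, "dropped_coarse") <- nCoarse
  attr(out, "dropped_window") <- nWindow
  attr(out, "rejected") <- nRejected
  out
}

#' Identify well-surveyed tetrads
#'
#' A tetrad is well surveyed when at least `minSurveys` surveys within the
#' window each recorded at least `minSpecies` plant species. Surveys below
#' the species threshold are simply not counted (they do not disqualify the
#' tetrad).
#'
#' @param log survey log data.frame: tetrad_id, year, species_count
#' @param window inclusive year range
#' @param minSurveys minimum number of qualifying surveys (default 2)
#' @param minSpecies minimum species count per qualifying survey (default 50)
#' @return character vector of well-surveyed tetrad ids (possibly empty)
#' @export
identifyWellSurveyed <- function(log, window = c(1950, 2014),
                                 minSurveys = 2, minSpecies = 50) {
  if (nrow(log) == 0L) return(character())
  stopifnot(all(c("tetrad_id", "year", "species_count") %in% names(log)))
  ok <- log$year >= window[1] & log$year <= window[2] &
    log$species_count >= minSpecies
  counts <- table(log$tetrad_id[ok])
  sort(names(counts)[counts >= minSurveys])
}

#' Build the presence-absence table
#'
#' Cell values: present (1) where any record exists for (species, tetrad);
#' absent (0) where the tetrad is well surveyed but record-free for that
#' species. Tetrads that are neither well surveyed nor carrying any record
#' are excluded. Tetrads failing the well-surveyed test but holding records
#' are retained as presence rows for the recorded species — presence is
#' evidence regardless of survey effort — with `NA` in their record-free
#' cells (no inferred absence without effort); [speciesData()] returns the
#' complete rows per species.
#'
#' @param records tetrad-level records from [simplifyRecords()]
#' @param wellSurveyed character vector of well-surveyed tetrad ids
#' @param species character vector of focal species (columns of the table)
#' @param tetradCoords data.frame with tetrad_id, easting, northing for
#'   every tetrad appearing in the table
#' @return a [PresenceAbsence-class]
#' @export
buildPresenceAbsence <- function(records, wellSurveyed, species,
                                 tetradCoords) {
  if (length(species) == 0L)
    stop("species list is empty")
  records <- records[records$species %in% species, , drop = FALSE]
  tets <- sort(unique(c(wellSurveyed, records$tetrad_id)))
  if (!all(tets %in% tetradCoords$tetrad_id))
    stop("tetradCoords is missing coordinates for some tetrads")
  ws <- tets %in% wellSurveyed
  pa <- matrix(NA_integer_, length(tets), length(species),
               dimnames = list(tets, species))
  pa[ws, ] <- 0L
  if (nrow(records))
    pa[cbind(match(records$tetrad_id, tets),
             match(records$species, species))] <- 1L
  m <- match(tets, tetradCoords$tetrad_id)
  coords <- cbind(easting = tetradCoords$easting[m],
                  northing = tetradCoords$northing[m])
  new("PresenceAbsence", pa = pa, coords = coords, tetradId = tets,
      wellSurveyed = ws)
}

#' @rdname PresenceAbsence-accessors
#' @name PresenceAbsence-accessors
setMethod("paMatrix", "PresenceAbsence", function(x) x@pa)

#' @rdname PresenceAbsence-accessors
setMethod("siteCoords", "PresenceAbsence", function(x) x@coords)

#' @rdname PresenceAbsence-accessors
setMethod("tetradIds", "PresenceAbsence", function(x) x@tetradId)

#' @rdname PresenceAbsence-accessors
setMethod("speciesNames", "PresenceAbsence", function(x) colnames(x@pa))

#' @rdname PresenceAbsence-accessors
#' @details `speciesData` returns, for one species, the tetrads with known
#'   status: a data.frame with tetrad_id, easting, northing and `occ` (0/1),
#'   dropping tetrads whose status for that species is unknown.
setMethod("speciesData", "PresenceAbsence", function(x, species) {
  if (!species %in% colnames(x@pa))
    stop("unknown species '", species, "'")
  v <- x@pa[, species]
  keep <- !is.na(v)
  data.frame(tetrad_id = x@tetradId[keep],
             easting = x@coords[keep, 1L],
             northing = x@coords[keep, 2L],
             occ = as.integer(v[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "PresenceAbsence", function(object) {
  cat("PresenceAbsence:", nrow(object@pa), "tetrads x",
      ncol(object@pa), "species\n")
  cat("  well-surveyed tetrads:", sum(object@wellSurveyed), "\n")
  cat("  overall prevalence:",
      signif(mean(object@pa == 1L, na.rm = TRUE), 3), "\n")
})

#' Export a presence-absence table as CSV
#'
#' One row per tetrad: tetrad_id, easting, northing, then one 0/1 column
#' per species (`NA` where status is unknown).
#'
#' @param pa a [PresenceAbsence-class]
#' @param path output CSV path
#' @export
writePresenceAbsence <- function(pa, path) {
  df <- data.frame(tetrad_id = tetradIds(pa),
                   easting = siteCoords(pa)[, 1L],
                   northing = siteCoords(pa)[, 2L],
                   paMatrix(pa), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
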