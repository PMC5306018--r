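#' @import methods
NULL

#' GridStack: aligned raster layers on a common square grid
#'
#' A lightweight container for a stack of named raster layers sharing one
#' extent and cell size. Layers are stored as a 3-D array indexed
#' `[x, y, layer]` with the origin at the lower-left corner and 0-based cell
#' `[x0 + (i-1)*cs, x0 + i*cs)` half-open intervals along each axis. Each
#' layer carries a kind flag (`"continuous"` or `"categorical"`) and a
#' priority rank (1 = most important) used to break ties when pruning
#' collinear layers.
#'
#' @slot layers 3-D numeric array, third dimension named by layer.
#' @slot kind character vector, one of `"continuous"`/`"categorical"` per layer.
#' @slot priority numeric rank per layer; lower = kept preferentially.
#' @slot cellsize cell edge length in metres (default 1000 = 1-km cells).
#' @slot origin numeric length-2, (x, y) of the lower-left grid corner.
#'
#' @exportClass GridStack
setClass("GridStack",
  representation(
    layers = "array",
    kind = "character",
    priority = "numeric",
    cellsize = "numeric",
    origin = "numeric"
  )
)

setValidity("GridStack", function(object) {
  msgs <- character()
  d <- dim(object@layers)
  if (length(d) != 3L)
    msgs <- c(msgs, "layers must be a 3-D array [x, y, layer]")
  nl <- if (length(d) == 3L) d[3L] else 0L
  if (is.null(dimnames(object@layers)[[3L]]))
    msgs <- c(msgs, "third array dimension must be named (layer names)")
  if (length(object@kind) != nl)
    msgs <- c(msgs, "kind must have one entry per layer")
  if (!all(object@kind %in% c("continuous", "categorical")))
    msgs <- c(msgs, "kind entries must be 'continuous' or 'categorical'")
  if (length(object@priority) != nl)
    msgs <- c(msgs, "priority must have one entry per layer")
  if (length(object@origin) != 2L)
    msgs <- c(msgs, "origin must be length 2")
  if (length(object@cellsize) != 1L || object@cellsize <= 0)
    msgs <- c(msgs, "cellsize must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' SpeciesMap: one gridded per-species surface
#'
#' Holds a single species' gridded surface: either an occupancy probability
#' map (values in `[0, 1]`) or an abundance map in hectares covered per
#' square kilometre (numerically percent cover, `[0, 100]`). `NA` cells mean
#' no-data.
#'
#' @slot species species name.
#' @slot values matrix `[x, y]` of cell values.
#' @slot what `"occupancy"` or `"abundance"`.
#' @slot cellsize cell edge length in metres.
#' @slot origin numeric length-2 lower-left corner.
#'
#' @exportClass SpeciesMap
setClass("SpeciesMap",
  representation(
    species = "character",
    values = "matrix",
    what = "character",
    cellsize = "numeric",
    origin = "numeric"
  )
)

setValidity("SpeciesMap", function(object) {
  msgs <- character()
  if (!object@what %in% c("occupancy", "abundance"))
    msgs <- c(msgs, "what must be 'occupancy' or 'abundance'")
  v <- object@values[!is.na(object@values)]
  if (object@what == "occupancy" && length(v) && (min(v) < 0 || max(v) > 1))
    msgs <- c(msgs, "occupancy values must lie in [0, 1]")
  if (object@what == "abundance" && length(v) && min(v) < 0)
    msgs <- c(msgs, "abundance values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' LandscapeConfig: parameters for the virtual landscape simulator
#'
#' Defines one synthetic study system: a square grid of 1-km cells, a stack
#' of spatially autocorrelated environmental covariates, and a community of
#' virtual species whose occupancy follows a logistic response to the
#' covariates and whose abundance is a zero-inflated function of occupancy,
#' tree cover and pairwise biotic interactions.
#'
#' @slot gridSize cells per side (>= 8).
#' @slot nCovariates number of continuous covariate layers.
#' @slot autocorrRange autocorrelation range of the Gaussian fields, in cells.
#' @slot nSpecies number of virtual species (>= 2).
#' @slot seed master seed; identical seeds give bit-identical landscapes.
#' @slot zeroFloor occupancy probability below which true abundance is 0.
#' @slot betaSd scale of the logistic occupancy coefficients (signal strength).
#' @slot interactionStrength magnitude of competitive interaction coefficients.
#' @slot nInteractions number of (directed) nonzero interaction pairs.
#' @slot prevalenceRange range of target species prevalences.
#'
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(
    gridSize = "integer",
    nCovariates = "integer",
    autocorrRange = "numeric",
    nSpecies = "integer",
    seed = "integer",
    zeroFloor = "numeric",
    betaSd = "numeric",
    interactionStrength = "numeric",
    nInteractions = "integer",
    prevalenceRange = "numeric"
  )
)

setValidity("LandscapeConfig", function(object) {
  msgs <- character()
  if (object@gridSize < 8L)
    msgs <- c(msgs, "gridSize must be at least 8")
  if (object@nSpecies < 2L)
    msgs <- c(msgs, "nSpecies must be at least 2")
  if (object@nCovariates < 1L)
    msgs <- c(msgs, "nCovariates must be at least 1")
  if (object@zeroFloor < 0 || object@zeroFloor > 1)
    msgs <- c(msgs, "zeroFloor must lie in [0, 1]")
  if (length(object@prevalenceRange) != 2L)
    msgs <- c(msgs, "prevalenceRange must be length 2")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: the generating surfaces of a virtual community
#'
#' Stores, per species, the true occupancy probability surface, the realized
#' presence grid drawn from it, and the true abundance surface (ha covered
#' per km^2, equal to percent cover); plus the signed interaction matrix, the
#' four tree-cover covariate layers (C_A all trees, C_W woodland trees, C_O
#' trees outside woodland, C_E woodland edge; all fractions in [0, 1]) and
#' the ancillary woodland-area and linear-feature fraction layers used when
#' harmonizing the two abundance survey dialects.
#'
#' @slot occupancy named list of matrices, true P(x) in [0, 1] per species.
#' @slot presence named list of 0/1 matrices, realized occupancy.
#' @slot abundance named list of matrices, true cover in [0, 100].
#' @slot interactions signed n x n matrix; entry [j, k] is the effect of
#'   species k's occupancy on species j's abundance.
#' @slot cover `GridStack` with layers C_A, C_W, C_O, C_E,
#'   woodland_fraction, linear_fraction.
#' @slot coefficients list of generating coefficients per species.
#' @slot zeroFloor the occupancy floor used for zero inflation.
#' @slot cellsize,origin grid geometry shared by all surfaces.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    occupancy = "list",
    presence = "list",
    abundance = "list",
    interactions = "matrix",
    cover = "GridStack",
    coefficients = "list",
    zeroFloor = "numeric",
    cellsize = "numeric",
    origin = "numeric"
  )
)

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  sp <- names(object@occupancy)
  if (!identical(sp, names(object@abundance)) ||
      !identical(sp, names(object@presence)))
    msgs <- c(msgs, "occupancy, presence and abundance must share species names")
  dims <- lapply(object@occupancy, dim)
  if (length(unique(dims)) > 1L)
    msgs <- c(msgs, "all occupancy surfaces must share the grid")
  for (s in sp) {
    p <- object@occupancy[[s]]
    a <- object@abundance[[s]]
    if (!identical(dim(p), dim(a))) {
      msgs <- c(msgs, "occupancy and abundance grids differ")
      break
    }
    if (any(p < 0 | p > 1)) msgs <- c(msgs, "occupancy outside [0, 1]")
    if (any(a < 0 | a > 100)) msgs <- c(msgs, "abundance outside [0, 100]")
    if (any(a[p < object@zeroFloor] != 0))
      msgs <- c(msgs, "abundance must be 0 below the occupancy floor")
  }
  if (!identical(dim(object@interactions),
                 c(length(sp), length(sp))))
    msgs <- c(msgs, "interaction matrix must be n_species x n_species")
  if (length(msgs)) unique(msgs) else TRUE
})

#' PresenceAbsence: sites-by-species binary table
#'
#' The stage-1 training substrate: one row per tetrad (2 x 2 km block of
#' four 1-km cells) with its centroid coordinates, one 0/1 column per
#' species. Rows failing the well-surveyed criterion may still carry
#' presences (a record is evidence regardless of survey effort) but their
#' record-free cells are `NA`, never inferred absences; use
#' [speciesData()] to obtain the complete presence-absence rows for one
#' species.
#'
#' @slot pa integer matrix, sites x species, entries 0/1/NA.
#' @slot coords matrix, sites x 2 (easting, northing of tetrad centroids).
#' @slot tetradId character vector of tetrad identifiers.
#' @slot wellSurveyed logical vector per site.
#'
#' @exportClass PresenceAbsence
setClass("PresenceAbsence",
  representation(
    pa = "matrix",
    coords = "matrix",
    tetradId = "character",
    wellSurveyed = "logical"
  )
)

setValidity("PresenceAbsence", function(object) {
  msgs <- character()
  n <- nrow(object@pa)
  if (nrow(object@coords) != n || length(object@tetradId) != n ||
      length(object@wellSurveyed) != n)
    msgs <- c(msgs, "pa, coords, tetradId and wellSurveyed must agree in length")
  vals <- object@pa[!is.na(object@pa)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msgs <- c(msgs, "pa entries must be 0, 1 or NA")
  if (any(is.na(object@pa[object@wellSurveyed, ])))
    msgs <- c(msgs, "well-surveyed rows must have no missing cells")
  if (is.null(colnames(object@pa)))
    msgs <- c(msgs, "pa must have species column names")
  if (length(msgs)) msgs else TRUE
})

#' FittedSDM: one algorithm-by-repeat species distribution model
#'
#' One member of the candidate set: a single algorithm fitted to the
#' training 70% of one random split, together with its held-out ROC AUC and
#' true skill statistic once scored. The predictor maps a covariate table to
#' a score in `[0, 1]`.
#'
#' @slot algorithm one of `glm`, `gam`, `cta`, `gbm`, `rf`, `maxent_like`.
#' @slot repeatIndex which of the repeated random splits this fit belongs to.
#' @slot fit the underlying fitted model object.
#' @slot covariates covariate column names used at fit time.
#' @slot catLevels list of factor levels per categorical covariate.
#' @slot trainIdx row indices of the training partition.
#' @slot seed the split/fit seed.
#' @slot roc,tss,tssThreshold held-out scores (`NA` until scored).
#'
#' @exportClass FittedSDM
setClass("FittedSDM",
  representation(
    algorithm = "character",
    repeatIndex = "integer",
    fit = "ANY",
    covariates = "character",
    catLevels = "list",
    trainIdx = "integer",
    seed = "integer",
    roc = "numeric",
    tss = "numeric",
    tssThreshold = "numeric"
  ),
  prototype(roc = NA_real_, tss = NA_real_, tssThreshold = NA_real_)
)

#' EnsembleSDM: ROC-weighted committee of selected SDMs
#'
#' The surviving members after leading-group/top-20 selection and consensus
#' rejection, refitted on 100% of the presence-absence data, with weights
#' proportional to each member's held-out ROC AUC (normalized to sum to 1).
#'
#' @slot species focal species name.
#' @slot members list of [FittedSDM-class] objects.
#' @slot weights numeric weights, `>= 0`, summing to 1.
#'
#' @exportClass EnsembleSDM
setClass("EnsembleSDM",
  representation(
    species = "character",
    members = "list",
    weights = "numeric"
  )
)

setValidity("EnsembleSDM", function(object) {
  msgs <- character()
  if (length(object@members) < 1L)
    msgs <- c(msgs, "ensemble needs at least one member")
  if (length(object@weights) != length(object@members))
    msgs <- c(msgs, "one weight per member required")
  if (any(object@weights < 0))
    msgs <- c(msgs, "weights must be non-negative")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-8)
    msgs <- c(msgs, "weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' AbundanceModel: stage-2 random-forest regression for one focal species
#'
#' A bagged regression-tree ensemble of harmonized percent-cover abundance
#' on the focal species' predicted occupancy, every other species' predicted
#' occupancy, and the four tree-cover covariates C_A, C_W, C_O, C_E.
#'
#' @slot focal focal species name.
#' @slot covariates ordered covariate names (focal P-hat first, remaining
#'   species in canonical name order, then C_A, C_W, C_O, C_E).
#' @slot fit the fitted forest.
#' @slot nTrain number of training rows.
#' @slot nNonzero number of training rows with nonzero abundance.
#' @slot seed fit seed.
#'
#' @exportClass AbundanceModel
setClass("AbundanceModel",
  representation(
    focal = "character",
    covariates = "character",
    fit = "ANY",
    nTrain = "integer",
    nNonzero = "integer",
    seed = "integer"
  )
)

#' CVReport: k-fold cross-validation summary for an abundance model
#'
#' Per-fold and pooled root-mean-square error and mean absolute error, both
#' in the units of the response (ha covered per km^2, = percent cover), plus
#' a predictive R-squared that is always flagged: with heavily zero-inflated
#' abundance data R-squared is dominated by the mass of zeros and understates
#' model usefulness, so RMSE/MAE are the headline metrics.
#'
#' @slot k number of folds.
#' @slot folds data.frame with columns fold, n, rmse, mae.
#' @slot rmse,mae pooled over all held-out predictions.
#' @slot r2 pooled predictive R-squared (1 - SSE/SST; can be negative).
#' @slot r2Caveat always `TRUE`: R-squared is unreliable under zero inflation.
#' @slot seed fold-assignment seed.
#'
#' @exportClass CVReport
setClass("CVReport",
  representation(
    k = "integer",
    folds = "data.frame",
    rmse = "numeric",
    mae = "numeric",
    r2 = "numeric",
    r2Caveat = "logical",
    seed = "integer"
  )
)

setValidity("CVReport", function(object) {
  msgs <- character()
  if (object@k < 2L) msgs <- c(msgs, "k must be >= 2")
  if (nrow(object@folds) &&
      any(object@folds$rmse + 1e-12 < object@folds$mae))
    msgs <- c(msgs, "per-fold RMSE must be >= MAE")
  if (length(msgs)) msgs else TRUE
})
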