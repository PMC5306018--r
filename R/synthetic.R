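## Virtual-species landscape simulator. Generates the statistical structure
## the two modelling stages assume: spatially autocorrelated environmental
## fields, logistic occupancy surfaces, zero-inflated abundance surfaces with
## pairwise biotic interactions, tree-cover covariate layers derived from a
## fine-scale woodland mask, effort-dependent presence-only sampling and
## abundance surveys in two source dialects.

#' Create a landscape configuration
#'
#' @param gridSize cells per side of the square 1-km grid (>= 8)
#' @param nCovariates number of continuous environmental layers
#' @param autocorrRange Gaussian-field autocorrelation range, in cells
#' @param nSpecies number of virtual species (>= 2)
#' @param seed master seed; the same seed gives bit-identical outputs
#' @param zeroFloor occupancy below which true abundance is zero (zero
#'   inflation; default 0.3)
#' @param betaSd scale of occupancy coefficients: larger = stronger
#'   environmental signal
#' @param interactionStrength magnitude of competitive effects on abundance
#' @param nInteractions number of directed nonzero interaction pairs
#' @param prevalenceRange range the species' target prevalences are drawn from
#' @return a [LandscapeConfig-class]
#' @export
landscapeConfig <- function(gridSize = 32, nCovariates = 6, autocorrRange = 6,
                            nSpecies = 5, seed = 1, zeroFloor = 0.3,
                            betaSd = 2, interactionStrength = 1,
                            nInteractions = nSpecies,
                            prevalenceRange = c(0.3, 0.55)) {
  new("LandscapeConfig",
      gridSize = as.integer(gridSize), nCovariates = as.integer(nCovariates),
      autocorrRange = autocorrRange, nSpecies = as.integer(nSpecies),
      seed = as.integer(seed), zeroFloor = zeroFloor, betaSd = betaSd,
      interactionStrength = interactionStrength,
      nInteractions = as.integer(nInteractions),
      prevalenceRange = prevalenceRange)
}

setMethod("show", "LandscapeConfig", function(object) {
  cat("LandscapeConfig:", object@gridSize, "x", object@gridSize, "cells,",
      object@nCovariates, "covariates,", object@nSpecies, "species, seed",
      object@seed, "\n")
})

#' Stationary Gaussian random field on a torus
#'
#' Smooths white noise with a Gaussian kernel by circular FFT convolution,
#' then standardizes to mean 0, sd 1. The lag correlation is monotone in
#' `range`. Draws from the current RNG state.
#'
#' @param n grid side length
#' @param range kernel standard deviation in cells; 0 returns white noise
#' @return an n x n matrix
#' @export
gaussianField <- function(n, range) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (range <= 0) return((z - mean(z)) / stats::sd(z))
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-outer(d^2, d^2, "+") / (2 * range^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)),
                     inverse = TRUE)) / (n * n)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the environmental covariate stack
#'
#' `nCovariates` independent spatially autocorrelated continuous fields
#' (standardized Gaussian fields) plus one categorical habitat layer built
#' by quartile-binning a further smoothed field. Deterministic under the
#' config seed.
#'
#' @param config a [LandscapeConfig-class]
#' @return a [GridStack-class]; continuous layers `env01...`, categorical
#'   layer `habitat`. Priorities follow layer order.
#' @export
genCovariateStack <- function(config) {
  stopifnot(is(config, "LandscapeConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@gridSize
  layers <- list()
  for (i in seq_len(config@nCovariates))
    layers[[sprintf("env%02d", i)]] <- gaussianField(n, config@autocorrRange)
  hab <- gaussianField(n, config@autocorrRange)
  layers[["habitat"]] <- matrix(
    as.numeric(cut(hab, stats::quantile(hab, 0:4 / 4),
                   include.lowest = TRUE, labels = FALSE)), n, n)
  gridStack(layers,
            kind = c(rep("continuous", config@nCovariates), "categorical"),
            cellsize = 1000, origin = c(0, 0))
}

## pick the intercept giving mean(plogis(a + eta)) = prevalence
calibrateIntercept <- function(eta, prevalence) {
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - prevalence,
                 c(-30, 30))$root
}

#' Generate virtual species and tree-cover truth surfaces
#'
#' Each species' occupancy is `plogis` of a linear form of the continuous
#' covariates (coefficients drawn at scale `betaSd`, intercept calibrated to
#' a target prevalence); realized presence is a Bernoulli draw per cell.
#' True abundance (ha covered per km^2, = percent cover) is zero-inflated:
#' zero wherever occupancy is below `zeroFloor` or the species is absent,
#' otherwise a monotone power of occupancy above the floor, scaled by total
#' tree cover and multiplied by `exp` of the interaction-weighted competitor
#' occupancies, clipped to `[0, 100]`. Tree-cover layers (C_A, C_W, C_O,
#' C_E, plus woodland-area and linear-feature fractions) are derived from a
#' fine-scale woodland mask; the woodland-edge layer uses the 50-m edge rule
#' via [computeEdgeCover()].
#'
#' @param stack output of [genCovariateStack()]
#' @param config the same [LandscapeConfig-class]
#' @param fineFactor fine cells per 1-km cell side for the woodland mask
#'   (fine cell = 1000/fineFactor metres; must give resolution <= 50 m)
#' @param interactions optional nSpecies x nSpecies matrix overriding the
#'   randomly drawn interaction coefficients (entry `[j, k]` = effect of
#'   species k's occupancy on species j's abundance)
#' @return a [SyntheticTruth-class]
#' @export
genVirtualSpecies <- function(stack, config, fineFactor = 20,
                              interactions = NULL) {
  stopifnot(is(config, "LandscapeConfig"))
  set.seed(config@seed + 1L)
  n <- config@gridSize
  nsp <- config@nSpecies
  spNames <- sprintf("sp%02d", seq_len(nsp))
  contNames <- layerNames(stack)[layerKind(stack) == "continuous"]
  X <- sapply(contNames, function(nm) as.vector(getLayer(stack, nm)))

  ## tree-cover truth from a fine-scale woodland mask
  fineN <- n * fineFactor
  wField <- gaussianField(fineN, config@autocorrRange * fineFactor)
  mask <- (wField > stats::qnorm(1 - 0.30)) * 1L  # ~30% woodland
  blockMean <- function(m, f) {
    nc <- nrow(m) / f
    out <- matrix(0, nc, nc)
    for (dx in seq_len(f)) for (dy in seq_len(f))
      out <- out + m[seq(dx, by = f, length.out = nc),
                     seq(dy, by = f, length.out = nc)]
    out / f^2
  }
  woodFrac <- blockMean(mask, fineFactor)
  dens <- stats::plogis(gaussianField(n, config@autocorrRange))
  cW <- woodFrac * (0.4 + 0.6 * dens)
  cO <- (1 - woodFrac) * 0.25 * stats::plogis(gaussianField(n, config@autocorrRange))
  cA <- cW + cO
  cE <- computeEdgeCover(mask, distance = 50,
                         fineCellsize = 1000 / fineFactor, outCellsize = 1000)
  linFrac <- 0.2 * stats::plogis(gaussianField(n, config@autocorrRange))
  cover <- gridStack(
    list(C_A = cA, C_W = cW, C_O = cO, C_E = cE,
         woodland_fraction = woodFrac, linear_fraction = linFrac),
    kind = "continuous", cellsize = 1000, origin = gridOrigin(stack))

  ## interaction matrix: sparse directed competitive effects on abundance
  alpha <- matrix(0, nsp, nsp, dimnames = list(spNames, spNames))
  if (config@nInteractions > 0L && config@interactionStrength != 0) {
    pairs <- which(diag(nsp) == 0)
    pick <- sample(pairs, min(config@nInteractions, length(pairs)))
    alpha[pick] <- -config@interactionStrength * stats::runif(length(pick), 0.5, 1)
  }
  if (!is.null(interactions)) {
    stopifnot(identical(dim(interactions), dim(alpha)))
    alpha[] <- interactions
  }

  occ <- pres <- vector("list", nsp)
  coefs <- vector("list", nsp)
  names(occ) <- names(pres) <- names(coefs) <- spNames
  for (j in seq_len(nsp)) {
    beta <- stats::rnorm(length(contNames), 0, config@betaSd)
    prev <- stats::runif(1, config@prevalenceRange[1], config@prevalenceRange[2])
    eta <- as.vector(X %*% beta)
    a <- calibrateIntercept(eta, prev)
    P <- matrix(stats::plogis(a + eta), n, n)
    occ[[j]] <- P
    pres[[j]] <- matrix(stats::rbinom(n * n, 1L, P), n, n)
    coefs[[j]] <- list(beta = stats::setNames(beta, contNames),
                       intercept = a, prevalence = prev)
  }

  abund <- vector("list", nsp)
  names(abund) <- spNames
  floor0 <- config@zeroFloor
  for (j in seq_len(nsp)) {
    P <- occ[[j]]
    base <- matrix(0, n, n)
    ok <- P >= floor0 & pres[[j]] == 1L
    base[ok] <- ((P[ok] - floor0) / (1 - floor0))^1.2
    inter <- matrix(0, n, n)
    for (k in seq_len(nsp)) if (alpha[j, k] != 0)
      inter <- inter + alpha[j, k] * occ[[k]]
    a <- 100 * base * (0.25 + 0.75 * cA) * exp(inter)
    abund[[j]] <- pmin(pmax(a, 0), 100)
  }

  new("SyntheticTruth",
      occupancy = occ, presence = pres, abundance = abund,
      interactions = alpha, cover = cover, coefficients = coefs,
      zeroFloor = floor0, cellsize = 1000, origin = gridOrigin(stack))
}

#' @rdname SyntheticTruth-accessors
#' @name SyntheticTruth-accessors
setMethod("occupancyTruth", "SyntheticTruth", function(x) x@occupancy)

#' @rdname SyntheticTruth-accessors
setMethod("abundanceTruth", "SyntheticTruth", function(x) x@abundance)

#' @rdname SyntheticTruth-accessors
setMethod("presenceTruth", "SyntheticTruth", function(x) x@presence)

#' @rdname SyntheticTruth-accessors
setMethod("interactionMatrix", "SyntheticTruth", function(x) x@interactions)

#' @rdname SyntheticTruth-accessors
setMethod("coverLayers", "SyntheticTruth", function(x)
  subsetLayers(x@cover, c("C_A", "C_W", "C_O", "C_E")))

#' @rdname SyntheticTruth-accessors
setMethod("woodlandFraction", "SyntheticTruth", function(x)
  getLayer(x@cover, "woodland_fraction"))

#' @rdname SyntheticTruth-accessors
setMethod("linearFraction", "SyntheticTruth", function(x)
  getLayer(x@cover, "linear_fraction"))

setMethod("show", "SyntheticTruth", function(object) {
  n <- length(object@occupancy)
  d <- dim(object@occupancy[[1L]])
  cat("SyntheticTruth:", n, "species on a", d[1], "x", d[2], "grid\n")
  cat("  zero-inflation occupancy floor:", object@zeroFloor, "\n")
  cat("  nonzero interaction pairs:", sum(object@interactions != 0), "\n")
})

#' Enumerate the tetrads of a grid
#'
#' Tetrads are 2 x 2 blocks of 1-km cells, indexed from the lower-left;
#' trailing odd rows/columns of cells are not covered by any tetrad.
#'
#' @param dim grid dimension (nx, ny) in 1-km cells
#' @param cellsize,origin grid geometry
#' @return data.frame with tetrad_id, tx, ty, easting, northing (centroid)
#' @export
tetradGrid <- function(dim, cellsize = 1000, origin = c(0, 0)) {
  ntx <- dim[1] %/% 2L
  nty <- dim[2] %/% 2L
  g <- expand.grid(tx = seq_len(ntx), ty = seq_len(nty))
  data.frame(
    tetrad_id = sprintf("T%03d_%03d", g$tx, g$ty),
    tx = g$tx, ty = g$ty,
    easting = origin[1] + (2 * (g$tx - 1) + 1) * cellsize,
    northing = origin[2] + (2 * (g$ty - 1) + 1) * cellsize,
    stringsAsFactors = FALSE
  )
}

## tetrad-level realized occupancy: occupied if any member cell is occupied
tetradOccupied <- function(presence, tetrads) {
  vapply(seq_len(nrow(tetrads)), function(i) {
    ix <- (tetrads$tx[i] - 1L) * 2L
    iy <- (tetrads$ty[i] - 1L) * 2L
    any(presence[ix + (1:2), iy + (1:2)] == 1L)
  }, logical(1))
}

#' Default effort model for presence-only sampling
#'
#' @param meanSurveys Poisson mean of surveys per surveyed tetrad
#' @param minSurveys lower bound applied to the Poisson draw
#' @param detectionProb per-survey probability of recording an occupying
#'   species
#' @param undersurveyedFraction fraction of tetrads receiving no surveys
#' @param richnessMean,richnessSd normal parameters of each survey's total
#'   recorded plant species count (drives the well-surveyed filter)
#' @param yearRange calendar years surveys are drawn from
#' @param precisionMix probabilities of record precision classes
#'   (finer-than-tetrad, tetrad, coarser)
#' @return named list of effort parameters
#' @export
effortModel <- function(meanSurveys = 2.5, minSurveys = 0, detectionProb = 0.9,
                        undersurveyedFraction = 0.15, richnessMean = 75,
                        richnessSd = 20, yearRange = c(1950, 2014),
                        precisionMix = c(finer = 0.3, tetrad = 0.65,
                                         coarser = 0.05)) {
  list(meanSurveys = meanSurveys, minSurveys = minSurveys,
       detectionProb = detectionProb,
       undersurveyedFraction = undersurveyedFraction,
       richnessMean = richnessMean, richnessSd = richnessSd,
       yearRange = yearRange, precisionMix = precisionMix)
}

#' Sample presence-only occurrence records and a survey log
#'
#' Emulates atlas-style recording: each tetrad receives a number of
#' botanical surveys (some tetrads deliberately receive none); each survey
#' records a total plant species count, and each virtual species occupying
#' the tetrad (any member cell) is detected per survey with probability
#' `detectionProb`, producing a presence-only record whose spatial precision
#' class is drawn from `precisionMix`.
#'
#' @param truth a [SyntheticTruth-class]
#' @param effort an [effortModel()] list
#' @param seed sampling seed
#' @return list with `records` (species, tetrad_id, year, precision) and
#'   `log` (tetrad_id, year, species_count)
#' @export
sampleOccurrences <- function(truth, effort = effortModel(), seed = 1) {
  effort <- utils::modifyList(effortModel(), effort)
  set.seed(seed)
  d <- dim(truth@presence[[1L]])
  tets <- tetradGrid(d, truth@cellsize, truth@origin)
  nT <- nrow(tets)

  surveyed <- stats::runif(nT) >= effort$undersurveyedFraction
  nSurv <- ifelse(surveyed,
                  pmax(effort$minSurveys, stats::rpois(nT, effort$meanSurveys)),
                  0L)
  logRows <- data.frame(
    tetrad_id = rep(tets$tetrad_id, nSurv),
    year = sample(seq(effort$yearRange[1], effort$yearRange[2]),
                  sum(nSurv), replace = TRUE),
    species_count = pmax(0, round(stats::rnorm(sum(nSurv),
                                               effort$richnessMean,
                                               effort$richnessSd))),
    stringsAsFactors = FALSE
  )

  occTet <- sapply(truth@presence, tetradOccupied, tetrads = tets)
  rownames(occTet) <- tets$tetrad_id
  recs <- list()
  for (sp in colnames(occTet)) {
    occupied <- logRows$tetrad_id %in% tets$tetrad_id[occTet[, sp]]
    hit <- occupied & stats::runif(nrow(logRows)) < effort$detectionProb
    if (!any(hit)) next
    recs[[sp]] <- data.frame(
      species = sp,
      tetrad_id = logRows$tetrad_id[hit],
      year = logRows$year[hit],
      precision = sample(names(effort$precisionMix), sum(hit),
                         replace = TRUE, prob = effort$precisionMix),
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(species = character(), tetrad_id = character(),
               year = integer(), precision = character())
  rownames(records) <- NULL
  list(records = records, log = logRows)
}

#' Sample abundance records in two survey dialects
#'
#' Draws percent-cover abundance observations from the truth surfaces in
#' two source formats. Patch-dialect records report percent cover of the
#' species *within the woodland patch* of a cell, so harmonization must
#' multiply by the cell's woodland fraction; they are only drawn in cells
#' with woodland where the within-patch percentage is well defined
#' (truth cover <= 100 x woodland fraction). Plot-dialect records report a
#' linear-plot and a nonlinear-plot percentage whose mixture, weighted by
#' the cell's linear-feature fraction, recovers the harmonized value.
#' Gaussian noise of sd `noiseSd` (cover units) is applied on the
#' harmonized scale; with `noiseSd = 0` harmonization reproduces the truth
#' exactly.
#'
#' @param truth a [SyntheticTruth-class]
#' @param nPatchSource,nPlotSource record counts per dialect
#' @param noiseSd observation noise, ha/km^2
#' @param seed sampling seed
#' @return list with `patch` (species, cell_x, cell_y, patch_percent) and
#'   `plot` (species, cell_x, cell_y, linear_percent, nonlinear_percent)
#' @export
sampleAbundance <- function(truth, nPatchSource, nPlotSource, noiseSd = 0,
                            seed = 1) {
  if (nPatchSource < 0 || nPlotSource < 0)
    stop("record counts must be non-negative")
  set.seed(seed)
  spNames <- names(truth@abundance)
  d <- dim(truth@abundance[[1L]])
  W <- woodlandFraction(truth)
  L <- linearFraction(truth)

  drawCells <- function(nrec, valid) {
    ## valid: logical matrix per (cell); sample species then a valid cell
    sp <- sample(spNames, nrec, replace = TRUE)
    out <- data.frame(species = sp, cell_x = NA_integer_, cell_y = NA_integer_,
                      stringsAsFactors = FALSE)
    for (s in unique(sp)) {
      rows <- which(sp == s)
      cells <- which(valid[[s]])
      if (!length(cells)) cells <- seq_len(d[1] * d[2])
      pick <- sample(cells, length(rows), replace = TRUE)
      out$cell_x[rows] <- ((pick - 1L) %% d[1]) + 1L
      out$cell_y[rows] <- ((pick - 1L) %/% d[1]) + 1L
    }
    out
  }

  ## patch dialect: only where woodland exists and within-patch % <= 100
  validPatch <- lapply(spNames, function(s)
    W > 0.01 & truth@abundance[[s]] <= 100 * W)
  names(validPatch) <- spNames
  patch <- drawCells(nPatchSource, validPatch)
  aP <- mapply(function(s, x, y) truth@abundance[[s]][x, y],
               patch$species, patch$cell_x, patch$cell_y)
  wP <- W[cbind(patch$cell_x, patch$cell_y)]
  target <- pmin(pmax(aP + stats::rnorm(nPatchSource, 0, noiseSd), 0), 100 * wP)
  patch$patch_percent <- ifelse(wP > 0, target / wP, 0)

  validPlot <- lapply(spNames, function(s) matrix(TRUE, d[1], d[2]))
  names(validPlot) <- spNames
  plotRec <- drawCells(nPlotSource, validPlot)
  aQ <- mapply(function(s, x, y) truth@abundance[[s]][x, y],
               plotRec$species, plotRec$cell_x, plotRec$cell_y)
  lQ <- L[cbind(plotRec$cell_x, plotRec$cell_y)]
  tQ <- pmin(pmax(aQ + stats::rnorm(nPlotSource, 0, noiseSd), 0), 100)
  u <- stats::runif(nPlotSource, 0.6, 1.6)
  lin <- pmin(pmax(u * tQ, 0), 100)
  nonlin <- (tQ - lQ * lin) / (1 - lQ)
  bad <- !is.finite(nonlin) | nonlin < 0 | nonlin > 100
  lin[bad] <- tQ[bad]
  nonlin[bad] <- tQ[bad]
  plotRec$linear_percent <- lin
  plotRec$nonlinear_percent <- nonlin

  rownames(patch) <- rownames(plotRec) <- NULL
  list(patch = patch, plot = plotRec)
}
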