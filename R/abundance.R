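## Stage 2: random-forest regression of harmonized percent-cover abundance
## on every species' predicted occupancy probability plus the four
## tree-cover covariates, with a fold-count rule maintaining an average of
## five nonzero records per cross-validation fold.

#' Assemble the stage-2 feature table
#'
#' One row per requested cell; columns ordered as the model formula reads:
#' the focal species' predicted occupancy first, the remaining species'
#' predicted occupancies in canonical (sorted) name order, then the four
#' cover covariates C_A, C_W, C_O, C_E. Rows with any no-data value are
#' excluded; the excluded count is attached as attribute `excluded`.
#'
#' @param cells data.frame with columns cell_x, cell_y
#' @param occMaps named list of occupancy [SpeciesMap-class] objects, one
#'   per species
#' @param cover a [GridStack-class] with layers C_A, C_W, C_O, C_E
#' @param focal focal species name (must be in `names(occMaps)`)
#' @return data.frame of features (`Phat_<species>` columns then cover)
#' @export
assembleFeatures <- function(cells, occMaps, cover, focal) {
  if (!focal %in% names(occMaps))
    stop("missing occupancy map for focal species '", focal, "'")
  others <- sort(setdiff(names(occMaps), focal))
  ordered <- c(focal, others)
  idx <- cbind(cells$cell_x, cells$cell_y)
  out <- lapply(ordered, function(s) mapValues(occMaps[[s]])[idx])
  names(out) <- paste0("Phat_", ordered)
  for (nm in c("C_A", "C_W", "C_O", "C_E")) {
    if (!nm %in% layerNames(cover))
      stop("cover stack is missing layer '", nm, "'")
    out[[nm]] <- getLayer(cover, nm)[idx]
  }
  df <- as.data.frame(out, optional = TRUE)
  keep <- stats::complete.cases(df)
  res <- df[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- sum(!keep)
  attr(res, "cells") <- cells[keep, , drop = FALSE]
  attr(res, "keptRows") <- which(keep)
  res
}

#' Fold count maintaining five nonzero records per fold
#'
#' With at least `perFold * maxK` nonzero abundance records, the maximum
#' `maxK` folds are used; below that, the fold count drops to
#' `floor(nNonzero / perFold)` as long as at least `minNonzero` records
#' remain; with fewer, the model is refused (too little data for a
#' reliable abundance model). Refusal is a value, not an error.
#'
#' @param nNonzero number of nonzero abundance records
#' @param perFold target nonzero records per fold (default 5)
#' @param maxK maximum fold count (default 10)
#' @param minNonzero refusal threshold (default 30)
#' @return integer fold count, or `NA_integer_` for refusal
#' @examples
#' chooseFoldCount(42) # 8
#' chooseFoldCount(50) # 10
#' chooseFoldCount(9)  # NA (refused)
#' @export
chooseFoldCount <- function(nNonzero, perFold = 5, maxK = 10,
                            minNonzero = 30) {
  if (nNonzero >= perFold * maxK) return(as.integer(maxK))
  if (nNonzero >= minNonzero) return(as.integer(nNonzero %/% perFold))
  NA_integer_
}

#' Default stage-2 forest hyperparameters
#'
#' 500 trees and one third of the covariates tried per split.
#'
#' @return named list with `num_trees` and `mtry_frac`
#' @export
abundanceDefaults <- function() list(num_trees = 500, mtry_frac = 1 / 3)

#' Fit the stage-2 abundance random forest
#'
#' A bagged regression-tree ensemble (permutation importance recorded at
#' fit time), deterministic under `seed`. Predictions are clipped to be
#' non-negative; because tree averaging interpolates, they also never
#' exceed the maximum observed abundance. All-constant abundance yields a
#' degenerate model predicting the constant, with a warning.
#'
#' @param features feature table from [assembleFeatures()]
#' @param abundance response vector, ha/km^2 in `[0, 100]`
#' @param hyper overrides merged into [abundanceDefaults()]
#' @param seed fit seed
#' @param focal focal species name (bookkeeping)
#' @return an [AbundanceModel-class]
#' @export
fitAbundanceRF <- function(features, abundance, hyper = list(), seed = 1,
                           focal = "species") {
  if (nrow(features) != length(abundance))
    stop("features and abundance must agree in length")
  if (any(abundance < 0 | abundance > 100))
    stop("abundance must lie in [0, 100]")
  if (length(unique(abundance)) == 1L)
    warning("abundance is constant; the model degenerates to that constant")
  hyper <- utils::modifyList(abundanceDefaults(), hyper)
  p <- ncol(features)
  fit <- ranger::ranger(
    x = features, y = abundance,
    num.trees = hyper$num_trees,
    mtry = max(1L, floor(p * hyper$mtry_frac)),
    importance = "permutation",
    seed = seed, num.threads = 1)
  new("AbundanceModel", focal = focal, covariates = colnames(features),
      fit = fit, nTrain = nrow(features),
      nNonzero = sum(abundance != 0), seed = as.integer(seed))
}

#' Predict abundance for a feature table
#'
#' @param model an [AbundanceModel-class]
#' @param features feature table with the model's covariate columns
#' @return non-negative predictions, ha/km^2
#' @export
predictAbundance <- function(model, features) {
  missing <- setdiff(model@covariates, names(features))
  if (length(missing))
    stop("features missing covariate(s): ", paste(missing, collapse = ", "))
  p <- stats::predict(model@fit, data = features[model@covariates],
                      num.threads = 1)$predictions
  pmax(p, 0)
}

setMethod("show", "AbundanceModel", function(object) {
  cat("AbundanceModel:", object@focal, "-", object@nTrain, "rows (",
      object@nNonzero, "nonzero ),", length(object@covariates),
      "covariates\n")
})

#' k-fold cross-validation of the abundance forest
#'
#' Rows are assigned to `k` folds at random (unstratified); each fold is
#' predicted by a forest trained on the remaining folds. RMSE and MAE are
#' reported per fold and pooled over all held-out predictions, in response
#' units (ha/km^2). Predictive R-squared (1 - SSE/SST) is computed on the
#' pooled held-out predictions and always flagged: under zero-inflated
#' abundance it is dominated by the mass of zeros.
#'
#' @param features feature table
#' @param abundance response vector
#' @param k fold count (>= 2), e.g. from [chooseFoldCount()]
#' @param seed fold-assignment and fit seed
#' @param hyper forest hyperparameter overrides
#' @return a [CVReport-class]
#' @export
crossValidate <- function(features, abundance, k, seed = 1, hyper = list()) {
  if (is.na(k) || k < 2L)
    stop("k must be at least 2")
  n <- nrow(features)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  perFold <- data.frame(fold = seq_len(k), n = 0L, rmse = NA_real_,
                        mae = NA_real_)
  for (i in seq_len(k)) {
    hold <- fold == i
    fit <- suppressWarnings(fitAbundanceRF(
      features[!hold, , drop = FALSE], abundance[!hold],
      hyper = hyper, seed = seed + i))
    pred[hold] <- predictAbundance(fit, features[hold, , drop = FALSE])
    perFold$n[i] <- sum(hold)
    perFold$rmse[i] <- rmse(abundance[hold], pred[hold])
    perFold$mae[i] <- mae(abundance[hold], pred[hold])
  }
  r2 <- if (stats::var(abundance) > 0) rSquared(abundance, pred) else NA_real_
  new("CVReport", k = as.integer(k), folds = perFold,
      rmse = rmse(abundance, pred), mae = mae(abundance, pred),
      r2 = r2, r2Caveat = TRUE, seed = as.integer(seed))
}

setMethod("show", "CVReport", function(object) {
  cat("CVReport:", object@k, "folds; pooled RMSE",
      signif(object@rmse, 4), "MAE", signif(object@mae, 4), "\n")
  cat("  R-squared:", signif(object@r2, 3),
      "(caveat: unreliable under zero inflation)\n")
})

#' Permutation variable importance, ranked
#'
#' @param model an [AbundanceModel-class] (importance recorded at fit time)
#' @return data.frame (covariate, importance) in descending importance;
#'   ties broken by the model's covariate order
#' @export
variableImportance <- function(model) {
  imp <- ranger::importance(model@fit)
  ord <- order(-imp, match(names(imp), model@covariates))
  data.frame(covariate = names(imp)[ord], importance = as.numeric(imp[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict an abundance map
#'
#' Evaluates the fitted forest on every grid cell, assembling features from
#' the occupancy maps and cover layers. Cells with no-data features
#' propagate to `NA`. An optional cutoff coerces small predictions to zero
#' (choosing it is a user act; default none).
#'
#' @param model an [AbundanceModel-class]
#' @param occMaps named list of occupancy [SpeciesMap-class] objects
#' @param cover cover-layer [GridStack-class]
#' @param zeroCutoff predictions strictly below this become 0 (default
#'   `NULL` = no coercion)
#' @return a [SpeciesMap-class] of abundance (ha/km^2)
#' @export
predictAbundanceMap <- function(model, occMaps, cover, zeroCutoff = NULL) {
  d <- gridDim(cover)
  if (!all(vapply(occMaps, function(m) identical(dim(mapValues(m)), d),
                  logical(1))))
    stop("occupancy maps and cover layers must share the grid")
  cells <- expand.grid(cell_x = seq_len(d[1]), cell_y = seq_len(d[2]))
  feats <- assembleFeatures(cells, occMaps, cover, model@focal)
  kept <- attr(feats, "cells")
  p <- rep(NA_real_, nrow(cells))
  if (nrow(feats)) {
    pin <- predictAbundance(model, feats)
    if (!is.null(zeroCutoff)) pin[pin < zeroCutoff] <- 0
    p[(kept$cell_y - 1L) * d[1] + kept$cell_x] <- pin
  }
  speciesMap(model@focal, matrix(p, d[1], d[2]), "abundance",
             cellsize = cellSize(cover), origin = gridOrigin(cover))
}
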