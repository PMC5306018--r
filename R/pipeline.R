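## Two-stage orchestration: stage 1 turns presence-absence tables into
## ROC-weighted ensemble occupancy maps; stage 2 feeds those maps plus the
## tree-cover covariates into per-species abundance forests. Stages
## communicate through files (tables and gridded layers) so each is
## independently runnable, and every filtering step logs record counts.

#' Assemble a pipeline configuration
#'
#' All defaults follow the method's stated values: 15 repeated 70/30
#' splits per algorithm, six algorithms, pairwise-correlation pruning at
#' 0.7, leading-group gap 0.05 with top-20 fallback, consensus rejection
#' at 0.25 mean absolute deviation, 10-fold cross-validation capped by the
#' five-nonzero-per-fold rule with refusal below 30 nonzero records, and
#' abundance survey sizes of 9,800 patch-dialect plus 9,453 plot-dialect
#' records. The configuration round-trips losslessly through YAML.
#'
#' @param species species subset (`NULL` = all in the presence-absence
#'   table)
#' @param algorithms SDM algorithm names
#' @param repeats repeated random splits per algorithm (default 15)
#' @param splitFraction training fraction (default 0.7)
#' @param gap leading-group separation (default 0.05)
#' @param fallbackK fallback selection size (default 20)
#' @param corThreshold collinearity pruning threshold (default 0.7)
#' @param deviationThreshold consensus rejection threshold (default 0.25)
#' @param perFold,maxK,minNonzero fold-rule parameters (5, 10, 30)
#' @param zeroCutoff abundance-map zero-coercion cutoff (`NULL` = none)
#' @param window occurrence calendar window (default 1950-2014, inclusive)
#' @param minSurveys,minSpecies well-surveyed criterion (2 surveys of >= 50
#'   species)
#' @param nPatchSource,nPlotSource abundance record counts per dialect
#' @param noiseSd abundance observation noise, ha/km^2
#' @param seed master pipeline seed
#' @param hyper,abundanceHyper hyperparameter overrides for the two stages
#' @return a named list of class `pipelineConfig`
#' @export
pipelineConfig <- function(species = NULL, algorithms = sdmAlgorithms(),
                           repeats = 15, splitFraction = 0.7, gap = 0.05,
                           fallbackK = 20, corThreshold = 0.7,
                           deviationThreshold = 0.25, perFold = 5,
                           maxK = 10, minNonzero = 30, zeroCutoff = NULL,
                           window = c(1950, 2014), minSurveys = 2,
                           minSpecies = 50, nPatchSource = 9800,
                           nPlotSource = 9453, noiseSd = 1, seed = 1,
                           hyper = list(), abundanceHyper = list()) {
  structure(list(
    species = species, algorithms = algorithms,
    repeats = as.integer(repeats), splitFraction = splitFraction,
    gap = gap, fallbackK = as.integer(fallbackK),
    corThreshold = corThreshold, deviationThreshold = deviationThreshold,
    perFold = as.integer(perFold), maxK = as.integer(maxK),
    minNonzero = as.integer(minNonzero), zeroCutoff = zeroCutoff,
    window = as.integer(window), minSurveys = as.integer(minSurveys),
    minSpecies = as.integer(minSpecies),
    nPatchSource = as.integer(nPatchSource),
    nPlotSource = as.integer(nPlotSource), noiseSd = noiseSd,
    seed = as.integer(seed), hyper = hyper,
    abundanceHyper = abundanceHyper
  ), class = "pipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()] list
#' @param path YAML file path
#' @return `readPipelineConfig` returns the reconstructed config
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

## tetrad block indices from centroid coordinates
tetradIndices <- function(coordsDf, cellsize = 1000, origin = c(0, 0)) {
  cbind(tx = floor((coordsDf$easting - origin[1]) / (2 * cellsize)) + 1L,
        ty = floor((coordsDf$northing - origin[2]) / (2 * cellsize)) + 1L)
}

## deterministic even subsample of grid rows used for consensus rejection
consensusRows <- function(tab, maxCells = 4000L) {
  covCols <- setdiff(names(tab), c("cell_x", "cell_y"))
  ok <- which(stats::complete.cases(tab[covCols]))
  if (length(ok) > maxCells)
    ok <- ok[round(seq(1L, length(ok), length.out = maxCells))]
  tab[ok, , drop = FALSE]
}

#' Run stage 1: ensemble SDMs and occupancy maps for all species
#'
#' Per species: repeated 70/30 splits, one fit per algorithm per split,
#' ROC/TSS scoring on the held-out 30%, leading-group/top-20 selection,
#' map-consensus rejection, refit of the survivors on 100% of the data,
#' ROC-weighted ensemble, and a gridded occupancy prediction. Species with
#' fewer than one presence or one absence are skipped with a logged
#' reason.
#'
#' @param pa a [PresenceAbsence-class]
#' @param stack covariate [GridStack-class] (pruned internally at
#'   `corThreshold`)
#' @param config a [pipelineConfig()]
#' @param outDir optional output directory (scores CSV, maps, pruning
#'   report)
#' @return list: `maps` (named [SpeciesMap-class] list), `ensembles`,
#'   `scores` (species, algorithm, repeat, roc, tss, selected, rejected),
#'   `log` (per-species status and model counts), `stack` (pruned)
#' @export
runStage1 <- function(pa, stack, config = pipelineConfig(), outDir = NULL) {
  pruned <- pruneCorrelated(stack, config$corThreshold)
  gridTab <- gridCovariateTable(pruned)
  rejTab <- consensusRows(gridTab)
  speciesSet <- config$species
  if (is.null(speciesSet)) speciesSet <- speciesNames(pa)

  maps <- list(); ensembles <- list()
  scoresAll <- list(); logRows <- list()
  for (sp in speciesSet) {
    sd <- speciesData(pa, sp)
    nPres <- sum(sd$occ == 1L); nAbs <- sum(sd$occ == 0L)
    if (nPres < 1L || nAbs < 1L || nrow(sd) < 10L) {
      logRows[[sp]] <- data.frame(species = sp, status = "skipped",
                                  reason = "too few presences or absences",
                                  n_rows = nrow(sd), n_models = 0L)
      next
    }
    tets <- tetradIndices(sd, cellSize(pruned), gridOrigin(pruned))
    data <- cbind(occ = sd$occ, tetradCovariates(pruned, tets))

    models <- list(); rows <- list()
    for (r in seq_len(config$repeats)) {
      seedR <- config$seed + r
      sp12 <- splitData(nrow(data), config$splitFraction, seed = seedR)
      train <- data[sp12$train, , drop = FALSE]
      test <- data[sp12$test, , drop = FALSE]
      if (length(unique(train$occ)) < 2L || length(unique(test$occ)) < 2L)
        next
      for (alg in config$algorithms) {
        m <- fitAlgorithm(alg, train, hyper = config$hyper, seed = seedR,
                          repeatIndex = r, trainIdx = sp12$train)
        m <- scoreModel(m, test)
        models[[length(models) + 1L]] <- m
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, algorithm = alg, rep = r,
          roc = m@roc, tss = m@tss)
      }
    }
    scores <- do.call(rbind, rows)
    sel <- selectModels(scores[c("roc", "tss")], config$gap, config$fallbackK)
    keep <- rejectInconsistent(models[sel], rejTab,
                               config$deviationThreshold)
    finalIdx <- sel[keep]
    scores$selected <- seq_len(nrow(scores)) %in% sel
    scores$rejected <- seq_len(nrow(scores)) %in% setdiff(sel, finalIdx)

    refits <- lapply(finalIdx, function(i) {
      m <- models[[i]]
      fitAlgorithm(m@algorithm, data, hyper = config$hyper, seed = m@seed,
                   repeatIndex = m@repeatIndex)
    })
    ens <- buildEnsemble(refits, species = sp,
                         roc = vapply(models[finalIdx], function(m) m@roc,
                                      numeric(1)))
    maps[[sp]] <- predictOccupancy(ens, pruned)
    ensembles[[sp]] <- ens
    scoresAll[[sp]] <- scores
    logRows[[sp]] <- data.frame(species = sp, status = "fitted",
                                reason = "", n_rows = nrow(sd),
                                n_models = nrow(scores))
  }
  scores <- do.call(rbind, c(scoresAll, list(make.row.names = FALSE)))
  log <- do.call(rbind, c(logRows, list(make.row.names = FALSE)))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(scores, file.path(outDir, "sdm_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(log, file.path(outDir, "stage1_log.csv"),
                     row.names = FALSE)
    if (!is.null(attr(pruned, "pruneReport")))
      writePruneReport(pruned, file.path(outDir, "prune_report.csv"))
    for (sp in names(maps))
      writeAsciiGrid(mapValues(maps[[sp]]),
                     file.path(outDir, paste0("occupancy_", sp, ".asc")),
                     cellsize = cellSize(pruned),
                     origin = gridOrigin(pruned))
  }
  list(maps = maps, ensembles = ensembles, scores = scores, log = log,
       stack = pruned)
}

#' Run stage 2: abundance forests, cross-validation and abundance maps
#'
#' Per focal species: assemble the feature table at the harmonized record
#' cells, apply the fold-count rule (refusing species with too few nonzero
#' records), fit the abundance forest, cross-validate, and predict a
#' gridded abundance map.
#'
#' @param harmonized harmonized abundance records (species, cell_x,
#'   cell_y, cover, source) from [mergeSources()]
#' @param occMaps named list of stage-1 occupancy [SpeciesMap-class]
#'   objects (all species)
#' @param cover [GridStack-class] with C_A, C_W, C_O, C_E
#' @param config a [pipelineConfig()]
#' @param outDir optional output directory
#' @return list: `models`, `cvReports`, `maps`, `importance`, and
#'   `status` data.frame (species, n_records, n_nonzero, k, refused)
#' @export
runStage2 <- function(harmonized, occMaps, cover,
                      config = pipelineConfig(), outDir = NULL) {
  speciesSet <- config$species
  if (is.null(speciesSet)) speciesSet <- sort(unique(harmonized$species))
  models <- list(); cvReports <- list(); maps <- list(); importance <- list()
  status <- list()
  for (sp in speciesSet) {
    if (!sp %in% names(occMaps))
      stop("missing stage-1 occupancy map for species '", sp, "'")
    recs <- harmonized[harmonized$species == sp, , drop = FALSE]
    feats <- assembleFeatures(recs[c("cell_x", "cell_y")], occMaps, cover, sp)
    y <- recs$cover[attr(feats, "keptRows")]
    nNonzero <- sum(y != 0)
    k <- chooseFoldCount(nNonzero, config$perFold, config$maxK,
                         config$minNonzero)
    status[[sp]] <- data.frame(species = sp, n_records = length(y),
                               n_nonzero = nNonzero, k = k,
                               refused = is.na(k))
    if (is.na(k)) next
    fit <- fitAbundanceRF(feats, y, hyper = config$abundanceHyper,
                          seed = config$seed, focal = sp)
    models[[sp]] <- fit
    cvReports[[sp]] <- crossValidate(feats, y, k, seed = config$seed,
                                     hyper = config$abundanceHyper)
    importance[[sp]] <- variableImportance(fit)
    maps[[sp]] <- predictAbundanceMap(fit, occMaps, cover,
                                      zeroCutoff = config$zeroCutoff)
  }
  status <- do.call(rbind, c(status, list(make.row.names = FALSE)))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(status, file.path(outDir, "stage2_status.csv"),
                     row.names = FALSE)
    cvRows <- lapply(names(cvReports), function(sp) {
      cv <- cvReports[[sp]]
      data.frame(species = sp, k = cv@k, rmse = cv@rmse, mae = cv@mae,
                 r2 = cv@r2, r2_caveat = cv@r2Caveat)
    })
    if (length(cvRows)) {
      cvDf <- do.call(rbind, cvRows)
      utils::write.csv(cvDf, file.path(outDir, "cv_report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(cvDf, file.path(outDir, "cv_report.json"),
                           dataframe = "rows", digits = NA)
    }
    for (sp in names(importance))
      utils::write.csv(importance[[sp]],
                       file.path(outDir, paste0("importance_", sp, ".csv")),
                       row.names = FALSE)
    for (sp in names(maps))
      writeAsciiGrid(mapValues(maps[[sp]]),
                     file.path(outDir, paste0("abundance_", sp, ".asc")),
                     cellsize = cellSize(cover), origin = gridOrigin(cover))
  }
  list(models = models, cvReports = cvReports, maps = maps,
       importance = importance, status = status)
}

#' Run the full two-stage pipeline on a synthetic landscape
#'
#' Simulates a virtual landscape and community, samples occurrence and
#' abundance surveys, prepares the presence-absence table, runs both
#' stages, and (optionally) writes all tables, maps and a run manifest
#' under `outDir`. Fully deterministic under the config seeds.
#'
#' @param landscape a [LandscapeConfig-class]
#' @param config a [pipelineConfig()]
#' @param outDir optional output directory
#' @param effort an [effortModel()] list
#' @return list: `truth`, `pa`, `stage1`, `harmonized`, `stage2`,
#'   `counts` (record accounting at each filter)
#' @export
runPipeline <- function(landscape, config = pipelineConfig(),
                        outDir = NULL, effort = effortModel()) {
  stack <- genCovariateStack(landscape)
  truth <- genVirtualSpecies(stack, landscape)
  occ <- sampleOccurrences(truth, effort, seed = config$seed + 101L)
  recs <- suppressWarnings(simplifyRecords(occ$records, config$window))
  ws <- identifyWellSurveyed(occ$log, config$window, config$minSurveys,
                             config$minSpecies)
  tets <- tetradGrid(gridDim(stack), cellSize(stack), gridOrigin(stack))
  pa <- buildPresenceAbsence(recs, ws, names(occupancyTruth(truth)), tets)

  s1dir <- if (is.null(outDir)) NULL else file.path(outDir, "stage1")
  stage1 <- runStage1(pa, stack, config, outDir = s1dir)

  ab <- sampleAbundance(truth, config$nPatchSource, config$nPlotSource,
                        noiseSd = config$noiseSd,
                        seed = config$seed + 202L)
  harmonized <- mergeSources(ab$patch, ab$plot, woodlandFraction(truth),
                             linearFraction(truth))
  s2dir <- if (is.null(outDir)) NULL else file.path(outDir, "stage2")
  stage2 <- runStage2(harmonized, stage1$maps, coverLayers(truth), config,
                      outDir = s2dir)

  counts <- data.frame(
    step = c("raw_records", "tetrad_level", "well_surveyed_tetrads",
             "pa_rows", "abundance_records", "harmonized_records"),
    n = c(nrow(occ$records), nrow(recs), length(ws),
          nrow(paMatrix(pa)),
          config$nPatchSource + config$nPlotSource, nrow(harmonized))
  )

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.yaml")
    writePipelineConfig(config, cfgPath)
    writePresenceAbsence(pa, file.path(outDir, "presence_absence.csv"))
    utils::write.csv(harmonized, file.path(outDir, "harmonized_abundance.csv"),
                     row.names = FALSE)
    utils::write.csv(counts, file.path(outDir, "record_counts.csv"),
                     row.names = FALSE)
    manifest <- list(
      config_hash = unname(tools::md5sum(cfgPath)),
      landscape = list(gridSize = landscape@gridSize,
                       nCovariates = landscape@nCovariates,
                       nSpecies = landscape@nSpecies,
                       seed = landscape@seed),
      counts = counts,
      files = sort(list.files(outDir, recursive = TRUE))
    )
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
  }
  list(truth = truth, pa = pa, stage1 = stage1, harmonized = harmonized,
       stage2 = stage2, counts = counts)
}
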