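## Stage 1: ensemble species distribution modelling. Six algorithm families
## are fitted on repeated random 70/30 splits of the presence-absence data,
## scored on the held-out 30% by ROC AUC and the true skill statistic,
## filtered by the leading-group/top-20 selection rule and a map-consensus
## rejection step, refitted on 100% of the data, and combined into a
## ROC-weighted ensemble predicting occupancy probability per 1-km cell.

sdmAlgorithms <- function() c("glm", "gam", "cta", "gbm", "rf", "maxent_like")

#' Default SDM hyperparameters
#'
#' @return named list: `rf_num_trees` (500), `gbm_nrounds` (100),
#'   `gbm_depth` (3), `gbm_eta` (0.1), `cta_cp` (0.01), `gam_k` (5),
#'   `maxent_nfolds` (5). All overridable via the `hyper` argument of
#'   [fitAlgorithm()].
#' @export
sdmDefaults <- function() {
  list(rf_num_trees = 500, gbm_nrounds = 100, gbm_depth = 3, gbm_eta = 0.1,
       cta_cp = 0.01, gam_k = 5, maxent_nfolds = 5)
}

#' Random 70/30 train/test split
#'
#' Unstratified: rows are sampled without regard to class. The training set
#' has `round(fraction * n)` rows; train and test are disjoint and
#' exhaustive.
#'
#' @param n number of rows
#' @param fraction training fraction (default 0.7)
#' @param seed split seed
#' @return list with integer vectors `train` and `test`
#' @export
splitData <- function(n, fraction = 0.7, seed = 1) {
  if (n < 10L)
    stop("too few rows to split meaningfully (n < 10)")
  set.seed(seed)
  train <- sort(sample.int(n, round(fraction * n)))
  list(train = train, test = setdiff(seq_len(n), train))
}

## coerce newdata factors to the levels seen in training; unseen levels are
## mapped to the modal training level so every algorithm can predict
alignFactors <- function(newdata, catLevels) {
  for (nm in names(catLevels)) {
    v <- as.character(newdata[[nm]])
    lv <- catLevels[[nm]]$levels
    v[!v %in% lv & !is.na(v)] <- catLevels[[nm]]$mode
    newdata[[nm]] <- factor(v, levels = lv)
  }
  newdata
}

## expanded feature matrix for the penalized-regression MaxEnt surrogate:
## linear + quadratic + pairwise products of continuous covariates, plus
## categorical dummies
expandFeatures <- function(data, covariates) {
  isFac <- vapply(data[covariates], is.factor, logical(1))
  contC <- covariates[!isFac]
  M <- as.matrix(data[contC])
  out <- list(M)
  if (length(contC)) {
    sq <- M^2
    colnames(sq) <- paste0(contC, "_sq")
    out <- c(out, list(sq))
    if (length(contC) >= 2L) {
      cp <- utils::combn(contC, 2L)
      pr <- apply(cp, 2L, function(p) M[, p[1L]] * M[, p[2L]])
      colnames(pr) <- apply(cp, 2L, paste, collapse = "_x_")
      out <- c(out, list(pr))
    }
  }
  for (nm in covariates[isFac]) {
    dm <- stats::model.matrix(~ v - 1, data.frame(v = data[[nm]]))
    colnames(dm) <- paste0(nm, "_", levels(data[[nm]]))
    out <- c(out, list(dm))
  }
  do.call(cbind, out)
}

## plain dummy-coded matrix for xgboost
dummyMatrix <- function(data, covariates) {
  isFac <- vapply(data[covariates], is.factor, logical(1))
  out <- list(as.matrix(data[covariates[!isFac]]))
  for (nm in covariates[isFac]) {
    dm <- stats::model.matrix(~ v - 1, data.frame(v = data[[nm]]))
    colnames(dm) <- paste0(nm, "_", levels(data[[nm]]))
    out <- c(out, list(dm))
  }
  do.call(cbind, out)
}

#' Fit one SDM algorithm to training data
#'
#' The registry covers six families: `glm` (logistic regression), `gam`
#' (spline-basis additive logistic model via mgcv), `cta` (single
#' classification tree via rpart), `gbm` (gradient-boosted trees via
#' xgboost), `rf` (probability random forest via ranger) and `maxent_like`
#' (penalized logistic regression on an expanded feature set — linear,
#' quadratic and pairwise-product terms — standing in the MaxEnt slot of
#' the six-family ensemble, since the input here is presence-absence rather
#' than presence-background). All predictors return calibrated scores in
#' `[0, 1]`.
#'
#' @param name algorithm name (see [sdmDefaults()] registry)
#' @param data data.frame with 0/1 column `occ` plus covariates (factors
#'   for categorical layers); both classes must be present
#' @param hyper overrides merged into [sdmDefaults()]
#' @param seed fit seed (controls stochastic learners and penalty folds)
#' @param repeatIndex bookkeeping: which repeated split this fit belongs to
#' @param trainIdx bookkeeping: training row indices in the parent table
#' @return a [FittedSDM-class]
#' @export
fitAlgorithm <- function(name, data, hyper = list(), seed = 1,
                         repeatIndex = 1L, trainIdx = integer()) {
  if (!name %in% sdmAlgorithms())
    stop("unknown algorithm '", name, "'; registry: ",
         paste(sdmAlgorithms(), collapse = ", "))
  if (length(unique(data$occ)) < 2L)
    stop("training data contain a single class; cannot fit '", name, "'")
  hyper <- utils::modifyList(sdmDefaults(), hyper)
  covariates <- setdiff(names(data), "occ")
  data <- droplevels(data)
  catLevels <- list()
  for (nm in covariates) if (is.factor(data[[nm]])) {
    tb <- table(data[[nm]])
    catLevels[[nm]] <- list(levels = levels(data[[nm]]),
                            mode = names(tb)[which.max(tb)])
  }
  usable <- covariates[vapply(covariates, function(nm)
    !is.factor(data[[nm]]) || nlevels(data[[nm]]) >= 2L, logical(1))]
  set.seed(seed)
  fit <- switch(name,
    glm = stats::glm(
      stats::reformulate(usable, "occ"), data = data, family = stats::binomial()),
    gam = {
      mkTerms <- function(k) vapply(usable, function(nm) {
        if (is.factor(data[[nm]])) return(nm)
        nu <- length(unique(data[[nm]]))
        if (k > 0L && nu >= 8L) sprintf("s(%s, k = %d)", nm, k) else nm
      }, character(1))
      gamFit <- function(k, method) {
        f <- stats::as.formula(paste("occ ~", paste(mkTerms(k), collapse = "+")))
        mgcv::gam(f, data = data, family = stats::binomial(), method = method)
      }
      ## small samples can make the smoothness search numerically
      ## unstable; shrink the basis, then drop to the additive linear
      ## logistic limit, rather than fail
      fit <- try(gamFit(hyper$gam_k, "REML"), silent = TRUE)
      if (inherits(fit, "try-error"))
        fit <- try(gamFit(4L, "GCV.Cp"), silent = TRUE)
      if (inherits(fit, "try-error"))
        fit <- gamFit(0L, "GCV.Cp")
      fit
    },
    cta = rpart::rpart(
      stats::reformulate(usable, "occ"), data = transform(data, occ = factor(occ)),
      method = "class",
      control = rpart::rpart.control(cp = hyper$cta_cp, xval = 0)),
    gbm = {
      X <- dummyMatrix(data, usable)
      bst <- xgboost::xgb.train(
        params = xgboost::xgb.params(objective = "binary:logistic",
                                     max_depth = hyper$gbm_depth,
                                     learning_rate = hyper$gbm_eta,
                                     nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = data$occ, nthread = 1),
        nrounds = hyper$gbm_nrounds, verbose = 0)
      list(model = bst, featureNames = colnames(X))
    },
    rf = ranger::ranger(
      stats::reformulate(usable, "occ"),
      data = transform(data, occ = factor(occ, levels = c("0", "1"))),
      probability = TRUE, num.trees = hyper$rf_num_trees, seed = seed,
      num.threads = 1, respect.unordered.factors = "order"),
    maxent_like = {
      X <- expandFeatures(data, usable)
      minClass <- min(table(data$occ))
      nf <- min(hyper$maxent_nfolds, minClass)
      if (nf >= 2L) {
        ## class-stratified fold assignment keeps both classes in every fold
        foldid <- integer(nrow(X))
        for (cl in unique(data$occ))
          foldid[data$occ == cl] <-
            sample(rep_len(seq_len(nf), sum(data$occ == cl)))
        cv <- glmnet::cv.glmnet(X, data$occ, family = "binomial",
                                foldid = foldid)
        list(model = cv, featureNames = colnames(X), s = "lambda.1se")
      } else {
        fit <- glmnet::glmnet(X, data$occ, family = "binomial",
                              lambda = 0.01)
        list(model = fit, featureNames = colnames(X), s = 0.01)
      }
    }
  )
  new("FittedSDM", algorithm = name, repeatIndex = as.integer(repeatIndex),
      fit = fit, covariates = usable, catLevels = catLevels,
      trainIdx = as.integer(trainIdx), seed = as.integer(seed))
}

#' @rdname predictSDM
setMethod("predictSDM", "FittedSDM", function(object, newdata) {
  newdata <- alignFactors(newdata, object@catLevels)
  missing <- setdiff(object@covariates, names(newdata))
  if (length(missing))
    stop("newdata is missing covariate(s): ", paste(missing, collapse = ", "))
  p <- switch(object@algorithm,
    glm = stats::predict(object@fit, newdata, type = "response"),
    gam = as.numeric(stats::predict(object@fit, newdata, type = "response")),
    cta = stats::predict(object@fit, newdata, type = "prob")[, "1"],
    gbm = {
      X <- dummyMatrix(newdata, object@covariates)
      X <- X[, object@fit$featureNames, drop = FALSE]
      stats::predict(object@fit$model, xgboost::xgb.DMatrix(X, nthread = 1))
    },
    rf = stats::predict(object@fit, data = newdata,
                        num.threads = 1)$predictions[, "1"],
    maxent_like = {
      X <- expandFeatures(newdata, object@covariates)
      X <- X[, object@fit$featureNames, drop = FALSE]
      as.numeric(stats::predict(object@fit$model, X, s = object@fit$s,
                                type = "response"))
    }
  )
  pmin(pmax(as.numeric(p), 0), 1)
})

setMethod("show", "FittedSDM", function(object) {
  cat("FittedSDM:", object@algorithm, "(repeat", object@repeatIndex, ")")
  if (!is.na(object@roc))
    cat(" ROC", signif(object@roc, 3), "TSS", signif(object@tss, 3))
  cat("\n")
})

#' Score a fitted SDM on held-out data
#'
#' Fills the `roc`, `tss` and `tssThreshold` slots from predictions on the
#' test partition.
#'
#' @param fsdm a [FittedSDM-class]
#' @param testData held-out rows with column `occ`
#' @return the scored [FittedSDM-class]
#' @export
scoreModel <- function(fsdm, testData) {
  p <- predictSDM(fsdm, testData)
  fsdm@roc <- scoreROC(p, testData$occ)
  ts <- scoreTSS(p, testData$occ)
  fsdm@tss <- ts$tss
  fsdm@tssThreshold <- ts$threshold
  fsdm
}

#' Select ensemble members by the leading-group / top-20 rule
#'
#' Models are sorted by ROC. If some leading group (top g models by ROC) is
#' separated from the remainder by a gap of at least `gap` in ROC *and* at
#' least `gap` in TSS (minimum of the group versus maximum of the
#' remainder), the smallest such group is selected. Otherwise the top
#' `fallbackK` models by ROC are selected (all models if fewer), with ties
#' at the cut included.
#'
#' @param scores data.frame with numeric columns `roc` and `tss`
#' @param gap leading-group separation in score units (default 0.05)
#' @param fallbackK fallback selection size (default 20)
#' @return integer indices (rows of `scores`) of the selected models
#' @export
selectModels <- function(scores, gap = 0.05, fallbackK = 20) {
  n <- nrow(scores)
  if (n < 1L) stop("no scored models")
  if (n == 1L) return(1L)
  ord <- order(-scores$roc, -scores$tss)
  roc <- scores$roc[ord]
  tss <- scores$tss[ord]
  for (g in seq_len(n - 1L)) {
    if (roc[g] - roc[g + 1L] >= gap &&
        min(tss[seq_len(g)]) - max(tss[(g + 1L):n]) >= gap)
      return(sort(ord[seq_len(g)]))
  }
  k <- min(fallbackK, n)
  cutoff <- roc[k]
  sort(which(scores$roc >= cutoff))
}

#' Reject members disagreeing with the map consensus
#'
#' Replaces manual response-curve screening with an automated consensus
#' filter: each member's predicted map is compared with the cellwise median
#' map; members whose mean absolute deviation from the median exceeds
#' `deviationThreshold` are rejected, worst first, but never below a floor
#' of two survivors. With fewer than three members no rejection is
#' attempted.
#'
#' @param members list of [FittedSDM-class]
#' @param newdata covariate table for the evaluation cells
#' @param deviationThreshold maximum tolerated mean absolute deviation
#'   (default 0.25, occupancy-probability units)
#' @return logical keep vector along `members`
#' @export
rejectInconsistent <- function(members, newdata, deviationThreshold = 0.25) {
  m <- length(members)
  if (m < 3L) return(rep(TRUE, m))
  preds <- vapply(members, predictSDM, numeric(nrow(newdata)),
                  newdata = newdata)
  med <- apply(preds, 1L, stats::median)
  madv <- colMeans(abs(preds - med))
  keep <- rep(TRUE, m)
  for (i in order(-madv)) {
    if (sum(keep) <= 2L) break
    if (madv[i] > deviationThreshold) keep[i] <- FALSE
  }
  keep
}

#' Build a ROC-weighted ensemble
#'
#' Weights are proportional to each member's held-out ROC AUC, normalized
#' to sum to one; the ensemble prediction is the weighted mean of member
#' predictions (a convex combination, so it stays within the member range).
#'
#' @param members nonempty list of scored [FittedSDM-class] objects
#' @param species focal species name
#' @param roc optional ROC weights; defaults to the members' `roc` slots
#' @return an [EnsembleSDM-class]
#' @export
buildEnsemble <- function(members, species = "species", roc = NULL) {
  if (length(members) == 0L)
    stop("cannot build an ensemble from an empty member set")
  if (is.null(roc))
    roc <- vapply(members, function(m) m@roc, numeric(1))
  if (anyNA(roc))
    stop("all members must carry ROC scores")
  new("EnsembleSDM", species = species, members = members,
      weights = roc / sum(roc))
}

#' @rdname predictSDM
setMethod("predictSDM", "EnsembleSDM", function(object, newdata) {
  preds <- vapply(object@members, predictSDM, numeric(nrow(newdata)),
                  newdata = newdata)
  as.numeric(preds %*% object@weights)
})

setMethod("show", "EnsembleSDM", function(object) {
  algs <- table(vapply(object@members, function(m) m@algorithm, ""))
  cat("EnsembleSDM:", object@species, "-", length(object@members),
      "members (", paste(names(algs), algs, sep = ":", collapse = ", "), ")\n")
})

## full-grid covariate table in cell-major order (x fastest)
gridCovariateTable <- function(stack) {
  d <- gridDim(stack)
  kinds <- layerKind(stack)
  out <- lapply(layerNames(stack), function(nm) {
    v <- as.vector(getLayer(stack, nm))
    if (kinds[[nm]] == "categorical")
      factor(as.integer(v), levels = sort(unique(as.integer(v))))
    else v
  })
  names(out) <- layerNames(stack)
  cbind(expand.grid(cell_x = seq_len(d[1]), cell_y = seq_len(d[2])),
        as.data.frame(out, optional = TRUE))
}

#' Predict an occupancy map from an ensemble
#'
#' Evaluates the ROC-weighted mean prediction on every grid cell of the
#' covariate stack. Cells with missing covariate values propagate to
#' no-data (`NA`). Errors if the stack lacks a covariate any member was
#' fitted with.
#'
#' @param ensemble an [EnsembleSDM-class]
#' @param stack a [GridStack-class] covering the prediction extent
#' @return a [SpeciesMap-class] of occupancy probabilities
#' @export
predictOccupancy <- function(ensemble, stack) {
  needed <- unique(unlist(lapply(ensemble@members, function(m) m@covariates)))
  missing <- setdiff(needed, layerNames(stack))
  if (length(missing))
    stop("stack is missing fitted covariate(s): ",
         paste(missing, collapse = ", "))
  tab <- gridCovariateTable(stack)
  covCols <- setdiff(names(tab), c("cell_x", "cell_y"))
  complete <- stats::complete.cases(tab[covCols])
  p <- rep(NA_real_, nrow(tab))
  if (any(complete))
    p[complete] <- predictSDM(ensemble, tab[complete, , drop = FALSE])
  d <- gridDim(stack)
  speciesMap(ensemble@species, matrix(p, d[1], d[2]), "occupancy",
             cellsize = cellSize(stack), origin = gridOrigin(stack))
}

#' Response curves of an ensemble to each continuous covariate
#'
#' Sweeps one covariate across its observed range while holding the others
#' at their median (continuous) or mode (categorical), recording the
#' ensemble prediction — an export for manual plausibility inspection.
#'
#' @param ensemble an [EnsembleSDM-class]
#' @param data reference covariate table (e.g. the training rows)
#' @param nPoints sweep resolution
#' @return data.frame with columns covariate, value, prediction
#' @export
responseCurves <- function(ensemble, data, nPoints = 50) {
  covCols <- setdiff(names(data), c("occ", "cell_x", "cell_y"))
  isFac <- vapply(data[covCols], is.factor, logical(1))
  base <- data[1L, covCols, drop = FALSE]
  for (nm in covCols) {
    base[[nm]] <- if (isFac[[nm]]) {
      tb <- table(data[[nm]])
      factor(names(tb)[which.max(tb)], levels = levels(data[[nm]]))
    } else stats::median(data[[nm]], na.rm = TRUE)
  }
  out <- list()
  for (nm in covCols[!isFac]) {
    sweep <- seq(min(data[[nm]], na.rm = TRUE),
                 max(data[[nm]], na.rm = TRUE), length.out = nPoints)
    nd <- base[rep(1L, nPoints), , drop = FALSE]
    nd[[nm]] <- sweep
    out[[nm]] <- data.frame(covariate = nm, value = sweep,
                            prediction = predictSDM(ensemble, nd))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
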