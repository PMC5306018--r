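test_that("70/30 splits are disjoint, exhaustive and seed-stable", {
  s <- splitData(10, seed = 3)
  expect_length(s$train, 7)
  expect_length(s$test, 3)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_identical(splitData(10, seed = 3), s)
  expect_false(identical(splitData(10, seed = 4), s))
  expect_error(splitData(9), "too few")
})

test_that("every registry algorithm separates separable data perfectly", {
  toy <- separableToy(60)
  s <- splitData(nrow(toy), seed = 1)
  for (alg in c("glm", "gam", "cta", "gbm", "rf", "maxent_like")) {
    m <- suppressWarnings(
      fitAlgorithm(alg, toy[s$train, ], seed = 1,
                   hyper = list(rf_num_trees = 100, gbm_nrounds = 30)))
    m <- scoreModel(m, toy[s$test, ])
    expect_gte(m@roc, 0.999)
    p <- predictSDM(m, toy)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("uninformative covariates give chance-level AUC", {
  set.seed(2)
  n <- 1000
  dat <- data.frame(occ = sample(0:1, n, replace = TRUE),
                    env01 = rnorm(n), env02 = rnorm(n))
  s <- splitData(n, seed = 2)
  for (alg in c("glm", "rf")) {
    m <- fitAlgorithm(alg, dat[s$train, ], seed = 2,
                      hyper = list(rf_num_trees = 100))
    m <- scoreModel(m, dat[s$test, ])
    expect_lt(abs(m@roc - 0.5), 0.1)
  }
})

test_that("degenerate training data are refused with helpful errors", {
  toy <- separableToy(30)
  toy$occ <- 1L
  expect_error(fitAlgorithm("glm", toy), "single class")
  expect_error(fitAlgorithm("nnet", separableToy(30)), "registry")
})

test_that("leading-group selection and top-20 fallback follow the rule", {
  # a leading block separated in both scores is taken whole
  scores <- data.frame(roc = c(rep(0.9, 15), rep(0.8, 75)),
                       tss = c(rep(0.6, 15), rep(0.5, 75)))
  expect_equal(selectModels(scores, gap = 0.05, fallbackK = 20), 1:15)
  # uniformly spaced scores have no gap: top 20 by ROC
  n <- 90
  scores2 <- data.frame(roc = seq(0.95, 0.5, length.out = n),
                        tss = seq(0.7, 0.2, length.out = n))
  expect_length(selectModels(scores2), 20)
  expect_equal(selectModels(scores2), 1:20)
  # fewer models than the fallback: all selected
  scores3 <- data.frame(roc = seq(0.9, 0.6, length.out = 12),
                        tss = seq(0.6, 0.3, length.out = 12))
  expect_equal(selectModels(scores3), 1:12)
  # ties at the fallback cut are included
  scores4 <- data.frame(roc = c(rep(0.9, 3), rep(0.85, 4)),
                        tss = rep(0.5, 7))
  expect_length(selectModels(scores4, fallbackK = 5), 7)
})

test_that("selection matches the brute-force definition on random scores", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    roc <- round(runif(n, 0.5, 1), 2)
    tss <- round(runif(n, 0, 0.8), 2)
    got <- selectModels(data.frame(roc = roc, tss = tss),
                        gap = 0.05, fallbackK = 10)
    expect_equal(got, bruteSelect(roc, tss, gap = 0.05, fallbackK = 10))
  }
})

test_that("ensemble weights are ROC-proportional and predictions convex", {
  toy <- separableToy(60)
  s <- splitData(nrow(toy), seed = 5)
  ms <- lapply(c("glm", "rf", "cta"), function(alg)
    scoreModel(suppressWarnings(
      fitAlgorithm(alg, toy[s$train, ], seed = 5,
                   hyper = list(rf_num_trees = 50))), toy[s$test, ]))
  ens <- buildEnsemble(ms, species = "toy", roc = c(0.8, 0.6, 0.6))
  expect_equal(ens@weights, c(0.8, 0.6, 0.6) / 2)
  preds <- sapply(ms, predictSDM, newdata = toy)
  got <- predictSDM(ens, toy)
  expect_equal(got, as.numeric(preds %*% ens@weights))
  expect_true(all(got >= apply(preds, 1, min) - 1e-12))
  expect_true(all(got <= apply(preds, 1, max) + 1e-12))
  # single member: identity
  one <- buildEnsemble(ms[1], species = "toy", roc = 0.9)
  expect_equal(predictSDM(one, toy), preds[, 1])
  expect_error(buildEnsemble(list()), "empty")
  # the closed-form weighted mean: ROC 0.8 and 0.6, preds 1 and 0
  expect_equal(sum(c(0.8, 0.6) / 1.4 * c(1, 0)), 0.8 / 1.4)
})

test_that("consensus rejection drops the contrarian but keeps a quorum", {
  toy <- separableToy(80)
  s <- splitData(nrow(toy), seed = 6)
  flip <- toy
  flip$occ <- 1L - flip$occ
  agree <- suppressWarnings(lapply(1:3, function(i)
    fitAlgorithm("glm", toy[s$train, ], seed = i)))
  contrarian <- suppressWarnings(fitAlgorithm("glm", flip[s$train, ], seed = 9))
  keep <- rejectInconsistent(c(agree, list(contrarian)), toy,
                             deviationThreshold = 0.25)
  expect_equal(keep, c(TRUE, TRUE, TRUE, FALSE))
  # identical members: nothing rejected
  same <- suppressWarnings(
    lapply(1:3, function(i) fitAlgorithm("glm", toy[s$train, ], seed = 1)))
  expect_true(all(rejectInconsistent(same, toy, 0.25)))
  # adversarial committee can never drop below two survivors
  third <- toy
  third$occ <- sample(0:1, nrow(toy), replace = TRUE)
  spread <- list(agree[[1]], contrarian,
                 fitAlgorithm("glm", third[s$train, ], seed = 2))
  expect_gte(sum(rejectInconsistent(spread, toy, 0.0001)), 2)
})

test_that("occupancy maps stay in range and propagate no-data", {
  tw <- tinyTruth()
  occ <- sampleOccurrences(tw$truth,
                           effortModel(minSurveys = 2,
                                       undersurveyedFraction = 0),
                           seed = 2)
  recs <- simplifyRecords(occ$records)
  ws <- identifyWellSurveyed(occ$log)
  pa <- buildPresenceAbsence(recs, ws, names(presenceTruth(tw$truth)),
                             tetradGrid(gridDim(tw$stack)))
  sd1 <- speciesData(pa, "sp01")
  dat <- cbind(occ = sd1$occ, extractSiteCovariates(tw$stack, sd1))
  s <- splitData(nrow(dat), seed = 1)
  ms <- suppressWarnings(lapply(c("glm", "rf"), function(alg)
    scoreModel(fitAlgorithm(alg, dat[s$train, ], seed = 1,
                            hyper = list(rf_num_trees = 50)),
               dat[s$test, ])))
  ens <- buildEnsemble(ms, species = "sp01")
  map <- predictOccupancy(ens, tw$stack)
  v <- mapValues(map)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_false(anyNA(v))
  # poke a hole in a covariate: the cell goes no-data
  holed <- tw$stack
  holed@layers[3, 4, "env01"] <- NA
  mapH <- predictOccupancy(ens, holed)
  expect_true(is.na(mapValues(mapH)[3, 4]))
  # a stack missing a fitted covariate is refused by name
  expect_error(predictOccupancy(ens, subsetLayers(tw$stack, "env01")),
               "env02")
})

test_that("response curves sweep each continuous covariate", {
  toy <- separableToy(60)
  s <- splitData(nrow(toy), seed = 8)
  m <- suppressWarnings(
    scoreModel(fitAlgorithm("glm", toy[s$train, ], seed = 1),
               toy[s$test, ]))
  ens <- buildEnsemble(list(m), species = "toy")
  rc <- responseCurves(ens, toy, nPoints = 11)
  expect_setequal(unique(rc$covariate), c("env01", "env02"))
  expect_true(all(rc$prediction >= 0 & rc$prediction <= 1))
})
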