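## small helper: named occupancy maps with uniform random values
fakeOccMaps <- function(nSpecies, d = c(6, 6), seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(nSpecies))
  maps <- lapply(sp, function(s)
    speciesMap(s, matrix(runif(prod(d)), d[1], d[2]), "occupancy"))
  names(maps) <- sp
  maps
}

fakeCover <- function(d = c(6, 6), seed = 2) {
  set.seed(seed)
  cw <- matrix(runif(prod(d), 0, 0.5), d[1], d[2])
  co <- matrix(runif(prod(d), 0, 0.3), d[1], d[2])
  gridStack(list(C_A = cw + co, C_W = cw, C_O = co,
                 C_E = matrix(runif(prod(d), 0, 0.2), d[1], d[2])))
}

test_that("feature tables have the model's column order and width", {
  d <- c(6, 6)
  cells <- expand.grid(cell_x = 1:6, cell_y = 1:6)
  maps25 <- fakeOccMaps(25, d)
  f25 <- assembleFeatures(cells, maps25, fakeCover(d), "sp07")
  expect_equal(ncol(f25), 29) # 25 occupancy predictors + 4 cover layers
  expect_equal(names(f25)[1], "Phat_sp07")
  expect_equal(names(f25)[2:25],
               paste0("Phat_", sort(setdiff(names(maps25), "sp07"))))
  expect_equal(names(f25)[26:29], c("C_A", "C_W", "C_O", "C_E"))

  maps2 <- fakeOccMaps(2, d)
  expect_equal(ncol(assembleFeatures(cells, maps2, fakeCover(d), "sp01")), 6)
  # no-data occupancy removes the row and reports it
  holed <- maps2
  holed$sp02@values[2, 3] <- NA
  f <- assembleFeatures(cells, holed, fakeCover(d), "sp01")
  expect_equal(attr(f, "excluded"), 1)
  expect_equal(nrow(f), 35)
  expect_error(assembleFeatures(cells, maps2, fakeCover(d), "zz"), "zz")
})

test_that("the fold rule keeps five nonzero records per fold", {
  expect_equal(chooseFoldCount(42), 8L)
  expect_equal(chooseFoldCount(50), 10L)
  expect_true(is.na(chooseFoldCount(9)))
  # exhaustive agreement with the closed-form rule
  for (n in 0:500) {
    want <- if (n >= 50) 10L else if (n >= 30) as.integer(n %/% 5) else
      NA_integer_
    expect_identical(chooseFoldCount(n), want)
  }
})

test_that("the abundance forest recovers a linear occupancy signal", {
  set.seed(20)
  n <- 2000
  feats <- data.frame(Phat_a = runif(n), Phat_b = runif(n),
                      C_A = runif(n), C_W = runif(n),
                      C_O = runif(n), C_E = runif(n))
  y <- 10 * feats$Phat_a
  fit <- fitAbundanceRF(feats[1:1500, ], y[1:1500], seed = 20, focal = "a")
  pred <- predictAbundance(fit, feats[1501:2000, ])
  expect_lt(mae(y[1501:2000], pred), 1)
  expect_true(all(pred >= 0))
  # tree averaging interpolates: never exceeds the observed maximum
  expect_lte(max(pred), max(y[1:1500]))
  # the signal covariate dominates the importance ranking
  imp <- variableImportance(fit)
  expect_equal(imp$covariate[1], "Phat_a")
  # pure-noise covariates have negligible relative importance
  expect_lt(max(imp$importance[imp$covariate != "Phat_a"]),
            0.1 * imp$importance[1])
})

test_that("a strong competitor covariate ranks in the importance top 3", {
  set.seed(21)
  n <- 800
  feats <- data.frame(Phat_a = runif(n), Phat_b = runif(n),
                      Phat_c = runif(n), C_A = runif(n), C_W = runif(n),
                      C_O = runif(n), C_E = runif(n))
  y <- pmax(0, 40 * feats$Phat_a * exp(-2 * feats$Phat_b) + rnorm(n, 0, 1))
  y <- pmin(y, 100)
  fit <- fitAbundanceRF(feats, y, seed = 21, focal = "a")
  imp <- variableImportance(fit)
  expect_true("Phat_b" %in% imp$covariate[1:3])
})

test_that("degenerate and permuted responses behave as expected", {
  set.seed(22)
  n <- 300
  feats <- data.frame(Phat_a = runif(n), C_A = runif(n), C_W = runif(n),
                      C_O = runif(n), C_E = runif(n))
  expect_warning(fit0 <- fitAbundanceRF(feats, rep(0, n), seed = 1),
                 "constant")
  expect_true(all(predictAbundance(fit0, feats) == 0))
  # permuting the response destroys the fit
  y <- pmax(0, 10 * feats$Phat_a + rnorm(n, 0, 0.5))
  yPerm <- sample(y)
  fit <- fitAbundanceRF(feats[1:200, ], yPerm[1:200], seed = 2)
  r2 <- rSquared(yPerm[201:300],
                 predictAbundance(fit, feats[201:300, ]))
  expect_lt(r2, 0.2)
  expect_error(fitAbundanceRF(feats, rep(150, n)), "0, 100")
})

test_that("cross-validation pools errors correctly", {
  set.seed(23)
  n <- 200
  feats <- data.frame(Phat_a = runif(n, 0, 10), C_A = runif(n),
                      C_W = runif(n), C_O = runif(n), C_E = runif(n))
  # leakage by construction: the response is a feature
  y <- feats$Phat_a
  cv <- crossValidate(feats, y, k = 5, seed = 1,
                      hyper = list(mtry_frac = 1))
  expect_lt(cv@rmse, 0.5)
  expect_equal(cv@k, 5L)
  expect_true(all(cv@folds$rmse + 1e-12 >= cv@folds$mae))
  expect_true(cv@r2Caveat)
  expect_error(crossValidate(feats, y, k = 1), "at least 2")
  expect_error(crossValidate(feats, y, k = NA), "at least 2")
})

test_that("abundance maps clip, cut off and propagate no-data", {
  d <- c(6, 6)
  maps <- fakeOccMaps(3, d, seed = 5)
  cov <- fakeCover(d, seed = 6)
  cells <- expand.grid(cell_x = 1:6, cell_y = 1:6)
  feats <- assembleFeatures(cells, maps, cov, "sp01")
  set.seed(7)
  y <- pmin(100, pmax(0, 30 * feats$Phat_sp01 + rnorm(nrow(feats))))
  fit <- fitAbundanceRF(feats, y, seed = 3, focal = "sp01")
  raw <- predictAbundanceMap(fit, maps, cov)
  expect_true(all(mapValues(raw) >= 0, na.rm = TRUE))
  cut <- predictAbundanceMap(fit, maps, cov, zeroCutoff = 10)
  vRaw <- mapValues(raw); vCut <- mapValues(cut)
  expect_true(all(vCut[vRaw < 10] == 0))
  expect_equal(vCut[vRaw >= 10], vRaw[vRaw >= 10])
  # no-data occupancy propagates
  holed <- maps
  holed$sp02@values[1, 1] <- NA
  expect_true(is.na(mapValues(predictAbundanceMap(fit, holed, cov))[1, 1]))
  # grid mismatch is refused
  small <- fakeOccMaps(3, c(4, 4))
  expect_error(predictAbundanceMap(fit, small, cov), "share the grid")
})
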