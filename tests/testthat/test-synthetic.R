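test_that("generators are pure functions of config and seed", {
  lc <- landscapeConfig(gridSize = 16, nCovariates = 3, nSpecies = 2, seed = 5)
  s1 <- genCovariateStack(lc)
  s2 <- genCovariateStack(lc)
  expect_identical(s1@layers, s2@layers)
  t1 <- genVirtualSpecies(s1, lc)
  t2 <- genVirtualSpecies(s2, lc)
  expect_identical(occupancyTruth(t1), occupancyTruth(t2))
  expect_identical(abundanceTruth(t1), abundanceTruth(t2))
  o1 <- sampleOccurrences(t1, seed = 3)
  o2 <- sampleOccurrences(t2, seed = 3)
  expect_identical(o1, o2)
  a1 <- sampleAbundance(t1, 50, 50, seed = 4)
  a2 <- sampleAbundance(t2, 50, 50, seed = 4)
  expect_identical(a1, a2)
})

test_that("covariate stack has the requested layers and autocorrelation", {
  lc <- landscapeConfig(gridSize = 32, nCovariates = 15, nSpecies = 2, seed = 2)
  st <- genCovariateStack(lc)
  expect_equal(sum(layerKind(st) == "continuous"), 15)
  expect_gte(sum(layerKind(st) == "categorical"), 1)
  expect_true(all(is.finite(st@layers)))
  expect_error(genCovariateStack(
    landscapeConfig(gridSize = 4, nSpecies = 2)), "gridSize")

  # lag-1 autocorrelation grows with the autocorrelation range
  lag1 <- function(m) cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  short <- genCovariateStack(landscapeConfig(gridSize = 32, nCovariates = 4,
                                             autocorrRange = 1, seed = 9))
  long <- genCovariateStack(landscapeConfig(gridSize = 32, nCovariates = 4,
                                            autocorrRange = 16, seed = 9))
  mShort <- mean(sapply(1:4, function(i) lag1(short@layers[, , i])))
  mLong <- mean(sapply(1:4, function(i) lag1(long@layers[, , i])))
  expect_gt(mLong, mShort)
})

test_that("virtual species surfaces respect their ranges and zero floor", {
  tw <- tinyTruth()
  tr <- tw$truth
  for (sp in names(occupancyTruth(tr))) {
    P <- occupancyTruth(tr)[[sp]]
    A <- abundanceTruth(tr)[[sp]]
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(A >= 0 & A <= 100))
    expect_true(all(A[P < tr@zeroFloor] == 0))
  }
  cov <- coverLayers(tr)
  expect_setequal(layerNames(cov), c("C_A", "C_W", "C_O", "C_E"))
  expect_true(all(cov@layers >= 0 & cov@layers <= 1))
  # total tree cover decomposes into woodland and outside-woodland cover
  expect_equal(getLayer(cov, "C_A"),
               getLayer(cov, "C_W") + getLayer(cov, "C_O"))
})

test_that("abundance tracks own occupancy absent interactions", {
  lc <- landscapeConfig(gridSize = 24, nCovariates = 1, nSpecies = 2,
                        seed = 8, nInteractions = 0)
  st <- genCovariateStack(lc)
  tr <- genVirtualSpecies(st, lc)
  for (sp in names(occupancyTruth(tr))) {
    P <- as.vector(occupancyTruth(tr)[[sp]])
    A <- as.vector(abundanceTruth(tr)[[sp]])
    expect_gt(cor(P, A, method = "spearman"), 0.4)
  }
})

test_that("a strong competitor depresses abundance in its strongholds", {
  lc <- landscapeConfig(gridSize = 32, nCovariates = 3, nSpecies = 2, seed = 13)
  st <- genCovariateStack(lc)
  alpha <- matrix(0, 2, 2)
  alpha[1, 2] <- -3 # species 2 suppresses species 1
  tr <- genVirtualSpecies(st, lc, interactions = alpha)
  pA <- as.vector(occupancyTruth(tr)$sp01)
  pB <- as.vector(occupancyTruth(tr)$sp02)
  aA <- as.vector(abundanceTruth(tr)$sp01)
  # stratify on own occupancy so only competitor pressure varies
  band <- pA >= 0.5 & aA > 0
  hiB <- band & pB > median(pB[band])
  loB <- band & pB <= median(pB[band])
  expect_gt(sum(hiB), 10)
  expect_lt(mean(aA[hiB]), mean(aA[loB]))
})

test_that("occurrence sampling respects effort and detection", {
  tw <- tinyTruth()
  full <- effortModel(minSurveys = 2, detectionProb = 1,
                      undersurveyedFraction = 0)
  occ <- sampleOccurrences(tw$truth, full, seed = 6)
  for (sp in names(presenceTruth(tw$truth))) {
    truthTet <- trueTetradOccupancy(tw$truth, sp)
    recorded <- unique(occ$records$tetrad_id[occ$records$species == sp])
    expect_setequal(recorded, truthTet$tetrad_id[truthTet$occ == 1])
  }
  # zero effort anywhere produces no records at all
  none <- sampleOccurrences(tw$truth,
                            effortModel(undersurveyedFraction = 1), seed = 6)
  expect_equal(nrow(none$records), 0)
  expect_equal(nrow(none$log), 0)
})

test_that("noiseless abundance samples invert exactly through harmonization", {
  tw <- tinyTruth()
  tr <- tw$truth
  ab <- sampleAbundance(tr, 120, 120, noiseSd = 0, seed = 3)
  harm <- mergeSources(ab$patch, ab$plot, woodlandFraction(tr),
                       linearFraction(tr))
  truthAt <- mapply(function(s, x, y) abundanceTruth(tr)[[s]][x, y],
                    harm$species, harm$cell_x, harm$cell_y)
  expect_equal(harm$cover, unname(truthAt), tolerance = 1e-10)
  expect_error(sampleAbundance(tr, -1, 5), "non-negative")
})

test_that("a high occupancy floor reproduces the zero-heavy regime", {
  lc <- landscapeConfig(gridSize = 24, nCovariates = 4, nSpecies = 3,
                        seed = 21, zeroFloor = 0.75,
                        prevalenceRange = c(0.1, 0.2))
  st <- genCovariateStack(lc)
  tr <- genVirtualSpecies(st, lc)
  ab <- sampleAbundance(tr, 400, 400, noiseSd = 0, seed = 2)
  harm <- mergeSources(ab$patch, ab$plot, woodlandFraction(tr),
                       linearFraction(tr))
  expect_gt(mean(harm$cover == 0), 0.9)
})
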