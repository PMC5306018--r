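test_that("record simplification keys precision classes correctly", {
  recs <- data.frame(
    species = c("A", "A", "A", "A", "B"),
    tetrad_id = c("T1", "T1", "T2", "T1", "T1"),
    year = c(1960, 1980, 2000, 2020, 1990),
    precision = c("finer", "tetrad", "coarser", "tetrad", "tetrad")
  )
  out <- simplifyRecords(recs)
  # duplicates collapsed, the coarse record dropped, the 2020 record
  # outside the window dropped
  expect_equal(nrow(out), 2)
  expect_setequal(paste(out$species, out$tetrad_id), c("A T1", "B T1"))
  expect_equal(attr(out, "dropped_coarse"), 1)
  expect_equal(attr(out, "dropped_window"), 1)

  recs$precision[5] <- "hectad?"
  expect_warning(out2 <- simplifyRecords(recs), "unknown precision")
  expect_equal(attr(out2, "rejected"), 1)
})

test_that("well-surveyed criterion needs two qualifying surveys", {
  log1 <- data.frame(tetrad_id = "T1", year = c(1960, 1990),
                     species_count = c(60, 55))
  expect_equal(identifyWellSurveyed(log1), "T1")
  # second survey below 50 species does not count
  log2 <- data.frame(tetrad_id = "T1", year = c(1960, 1990),
                     species_count = c(60, 49))
  expect_equal(identifyWellSurveyed(log2), character())
  # one rich survey is not enough
  log3 <- data.frame(tetrad_id = "T1", year = 2000, species_count = 200)
  expect_equal(identifyWellSurveyed(log3), character())
  # a weak third survey does not disqualify two qualifying ones
  log4 <- data.frame(tetrad_id = "T1", year = c(1955, 1975, 1995),
                     species_count = c(60, 20, 70))
  expect_equal(identifyWellSurveyed(log4), "T1")
  expect_equal(identifyWellSurveyed(log1[0, ]), character())
})

test_that("raising the species threshold never enlarges the surveyed set", {
  set.seed(3)
  log <- data.frame(
    tetrad_id = sample(sprintf("T%02d", 1:30), 200, replace = TRUE),
    year = sample(1950:2014, 200, replace = TRUE),
    species_count = rpois(200, 55)
  )
  sets <- lapply(c(30, 40, 50, 60, 70), function(ms)
    identifyWellSurveyed(log, minSpecies = ms))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("presence-absence assembly treats presence and absence asymmetrically", {
  recs <- data.frame(species = c("A", "B", "A"),
                     tetrad_id = c("T1", "T1", "T3"))
  coords <- data.frame(tetrad_id = c("T1", "T2", "T3", "T4"),
                       easting = c(1, 3, 5, 7) * 1000,
                       northing = rep(1000, 4))
  pa <- buildPresenceAbsence(recs, wellSurveyed = c("T1", "T2"),
                             species = c("A", "B"), tetradCoords = coords)
  m <- paMatrix(pa)
  expect_equal(m["T1", "A"], 1L)            # recorded presence
  expect_equal(m["T2", "A"], 0L)            # well-surveyed, no record
  expect_equal(m["T3", "A"], 1L)            # presence kept despite poor effort
  expect_true(is.na(m["T3", "B"]))          # but no inferred absence there
  expect_false("T4" %in% tetradIds(pa))     # no record, not well-surveyed
  dA <- speciesData(pa, "A")
  expect_setequal(dA$tetrad_id, c("T1", "T2", "T3"))
  dB <- speciesData(pa, "B")
  expect_setequal(dB$tetrad_id, c("T1", "T2"))
  expect_error(buildPresenceAbsence(recs, "T1", character(), coords),
               "empty")
})

test_that("perfect detection with universal effort recovers true occupancy", {
  tw <- tinyTruth()
  full <- effortModel(minSurveys = 2, detectionProb = 1,
                      undersurveyedFraction = 0, richnessMean = 100,
                      richnessSd = 0)
  occ <- sampleOccurrences(tw$truth, full, seed = 9)
  recs <- simplifyRecords(occ$records)
  ws <- identifyWellSurveyed(occ$log)
  tets <- tetradGrid(gridDim(tw$stack))
  pa <- buildPresenceAbsence(recs, ws, names(presenceTruth(tw$truth)), tets)
  for (sp in speciesNames(pa)) {
    got <- speciesData(pa, sp)
    truth <- trueTetradOccupancy(tw$truth, sp)
    m <- merge(got, truth, by = "tetrad_id")
    expect_equal(m$occ.x, m$occ.y)
    # every tetrad is well-surveyed, so every tetrad has known status
    expect_equal(nrow(got), nrow(truth))
  }
})
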