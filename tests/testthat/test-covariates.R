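## build layers with an exact empirical correlation via Gram-Schmidt
makeCorrPair <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- scale(rnorm(n * n))[, 1]
  raw <- rnorm(n * n)
  z2 <- raw - sum(raw * z1) / sum(z1 * z1) * z1
  z2 <- scale(z2)[, 1]
  list(a = matrix(z1, n, n), b = matrix(r * z1 + sqrt(1 - r^2) * z2, n, n))
}

test_that("pruning removes the lower-priority member above the threshold", {
  p <- makeCorrPair(12, 0.71)
  st <- gridStack(list(x = p$a, y = p$b), priority = c(1, 2))
  out <- pruneCorrelated(st, 0.7)
  expect_equal(layerNames(out), "x")
  rep <- attr(out, "pruneReport")
  expect_equal(rep$removed, "y")
  expect_equal(rep$r, 0.71, tolerance = 1e-10)

  # priority decides, not order
  st2 <- gridStack(list(x = p$a, y = p$b), priority = c(2, 1))
  expect_equal(layerNames(pruneCorrelated(st2, 0.7)), "y")
})

test_that("a pair exactly at the threshold is retained", {
  p <- makeCorrPair(12, 0.7)
  st <- gridStack(list(x = p$a, y = p$b))
  expect_setequal(layerNames(pruneCorrelated(st, 0.7)), c("x", "y"))
})

test_that("mutually collinear trios collapse to the top priority layer", {
  set.seed(4)
  n <- 16
  base <- matrix(rnorm(n * n), n, n)
  st <- gridStack(list(u = base + matrix(rnorm(n * n, 0, 0.1), n, n),
                       v = base + matrix(rnorm(n * n, 0, 0.1), n, n),
                       w = base + matrix(rnorm(n * n, 0, 0.1), n, n)),
                  priority = c(3, 1, 2))
  out <- pruneCorrelated(st, 0.7)
  expect_equal(layerNames(out), "v")

  # brute-force oracle: the feasible retained subset with the best
  # priorities (here, any single layer; the greedy keeps the top one)
  vals <- sapply(c("u", "v", "w"), function(nm)
    as.vector(getLayer(st, nm)))
  feasible <- list()
  for (size in 3:1) {
    combos <- combn(colnames(vals), size, simplify = FALSE)
    for (cc in combos) {
      cm <- abs(cor(vals[, cc, drop = FALSE]))
      diag(cm) <- 0
      if (all(cm <= 0.7)) feasible <- c(feasible, list(cc))
    }
  }
  sizes <- lengths(feasible)
  best <- feasible[sizes == max(sizes)]
  expect_true(list(layerNames(out)) %in% lapply(best, identity) ||
                max(sizes) == 1)
  expect_equal(layerNames(out), "v") # highest priority among singletons
})

test_that("pruning is idempotent and the retained set satisfies the bound", {
  set.seed(5)
  n <- 16
  base <- matrix(rnorm(n * n), n, n)
  layers <- list(
    a = base, b = base * 0.9 + matrix(rnorm(n * n, 0, 0.4), n, n),
    c = matrix(rnorm(n * n), n, n),
    d = base * -0.95 + matrix(rnorm(n * n, 0, 0.2), n, n),
    cat = matrix(sample(1:3, n * n, TRUE), n, n)
  )
  st <- gridStack(layers, kind = c(rep("continuous", 4), "categorical"))
  out <- pruneCorrelated(st, 0.7)
  contNames <- names(layerKind(out))[layerKind(out) == "continuous"]
  cm <- abs(cor(sapply(contNames, function(nm) as.vector(getLayer(out, nm)))))
  diag(cm) <- 0
  expect_true(all(cm <= 0.7))
  # categorical layers pass through untouched
  expect_true("cat" %in% layerNames(out))
  out2 <- pruneCorrelated(out, 0.7)
  expect_identical(layerNames(out2), layerNames(out))
  expect_identical(out2@layers, out@layers)
})

test_that("constant layers are excluded from correlation with a warning", {
  set.seed(6)
  st <- gridStack(list(a = matrix(rnorm(64), 8),
                       flat = matrix(1, 8, 8)))
  expect_warning(out <- pruneCorrelated(st, 0.7), "constant")
  expect_setequal(layerNames(out), c("a", "flat"))
})

test_that("site extraction uses the half-open cell convention", {
  st <- gridStack(list(v = matrix(1:16, 4, 4)), cellsize = 1000)
  # cell centre
  expect_equal(extractSiteCovariates(
    st, data.frame(easting = 1500, northing = 500))$v, 2)
  # a point on the shared edge belongs to the upper cell
  expect_equal(extractSiteCovariates(
    st, data.frame(easting = 1000, northing = 0))$v, 2)
  expect_error(extractSiteCovariates(
    st, data.frame(easting = 4500, northing = 500)), "site 1")
  # constant layer gives a constant column
  st2 <- gridStack(list(k = matrix(7, 4, 4)))
  sites <- data.frame(easting = c(500, 2500), northing = c(500, 3500))
  expect_equal(extractSiteCovariates(st2, sites)$k, c(7, 7))
})
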