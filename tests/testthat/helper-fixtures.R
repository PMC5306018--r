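## Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

## a small 3-species landscape reused across module tests
tinyTruth <- function() {
  if (is.null(.fixtures$tiny)) {
    lc <- landscapeConfig(gridSize = 24, nCovariates = 4, nSpecies = 3,
                          seed = 42)
    st <- genCovariateStack(lc)
    .fixtures$tiny <- list(config = lc, stack = st,
                           truth = genVirtualSpecies(st, lc))
  }
  .fixtures$tiny
}

## separable binary classification toy data for the SDM registry
separableToy <- function(n = 60) {
  set.seed(11)
  occ <- rep(c(0L, 1L), each = n / 2)
  data.frame(
    occ = occ,
    env01 = occ * 10 + rnorm(n),
    env02 = rnorm(n),
    habitat = factor(sample(1:3, n, replace = TRUE), levels = 1:3)
  )
}

## brute-force ROC AUC: count correctly ordered presence-absence pairs
bruteAUC <- function(predicted, labels) {
  pos <- predicted[labels == 1]
  neg <- predicted[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## brute-force TSS: scan every distinct classification of the prediction set
bruteTSS <- function(predicted, labels) {
  thrs <- sort(unique(c(predicted, max(predicted) + 1)))
  best <- -Inf
  for (thr in thrs) {
    pos <- predicted >= thr
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

## brute-force per-cell nearest-nonwoodland distance scan for edge cover
bruteEdge <- function(mask, distance, fineCellsize) {
  nx <- nrow(mask); ny <- ncol(mask)
  nonIdx <- which(mask == 0, arr.ind = TRUE)
  edge <- matrix(FALSE, nx, ny)
  if (nrow(nonIdx) == 0) return(edge)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (mask[i, j] != 1) next
    d2 <- (nonIdx[, 1] - i)^2 + (nonIdx[, 2] - j)^2
    edge[i, j] <- min(d2) * fineCellsize^2 <= distance^2
  }
  edge
}

## brute-force leading-group/top-k selection following its definition
bruteSelect <- function(roc, tss, gap = 0.05, fallbackK = 20) {
  n <- length(roc)
  ord <- order(-roc, -tss)
  for (g in seq_len(n - 1)) {
    top <- ord[seq_len(g)]
    rest <- ord[(g + 1):n]
    if (roc[top[g]] - roc[rest[1]] >= gap &&
        min(tss[top]) - max(tss[rest]) >= gap)
      return(sort(top))
  }
  k <- min(fallbackK, n)
  cutoff <- sort(roc, decreasing = TRUE)[k]
  sort(which(roc >= cutoff))
}

## true tetrad-level occupancy: occupied if any member cell is occupied
trueTetradOccupancy <- function(truth, species) {
  pres <- presenceTruth(truth)[[species]]
  tets <- tetradGrid(dim(pres))
  occ <- vapply(seq_len(nrow(tets)), function(i) {
    ix <- (tets$tx[i] - 1L) * 2L
    iy <- (tets$ty[i] - 1L) * 2L
    any(pres[ix + (1:2), iy + (1:2)] == 1L)
  }, logical(1))
  data.frame(tetrad_id = tets$tetrad_id, occ = as.integer(occ))
}
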