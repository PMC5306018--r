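## Shared evaluation metrics for both pipeline stages. These are the
## package's own oracle-tested implementations; tests compare them against
## brute-force pair counting and exhaustive threshold search.

checkPairs <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 1L)
    stop("need at least one observation")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("values must be finite")
}

#' Root-mean-square error
#'
#' @param observed,predicted numeric vectors of equal length
#' @return `sqrt(mean((observed - predicted)^2))`
#' @examples
#' rmse(c(0, 4), c(2, 2)) # 2
#' @export
rmse <- function(observed, predicted) {
  checkPairs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(observed - predicted))`
#' @export
mae <- function(observed, predicted) {
  checkPairs(observed, predicted)
  mean(abs(observed - predicted))
}

#' Predictive R-squared (1 - SSE/SST)
#'
#' Computed against held-out observations, so it can be negative when
#' predictions are worse than the observed mean. Errors if the observed
#' values are constant (SST = 0).
#'
#' @inheritParams rmse
#' @return numeric
#' @export
rSquared <- function(observed, predicted) {
  checkPairs(observed, predicted)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("observed values are constant; R-squared is undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' ROC AUC by pair counting
#'
#' The probability that a randomly chosen presence is scored above a
#' randomly chosen absence, with ties counting one half — computed via the
#' rank-sum identity, which equals exhaustive counting over all
#' presence-absence pairs.
#'
#' @param predicted numeric scores
#' @param labels 0/1 vector
#' @return AUC in `[0, 1]`
#' @examples
#' scoreROC(c(0.1, 0.9), c(0, 1)) # 1
#' @export
scoreROC <- function(predicted, labels) {
  checkPairs(labels, predicted)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("ROC AUC undefined: labels contain a single class")
  r <- rank(predicted, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' True skill statistic with threshold optimization
#'
#' TSS = sensitivity + specificity - 1, maximized over a candidate threshold
#' set consisting of the midpoints between consecutive sorted unique
#' predictions plus the two endpoint values; a prediction counts as presence
#' when `score >= threshold`. On ties the smallest optimizing threshold is
#' reported.
#'
#' @inheritParams scoreROC
#' @return list with elements `tss` and `threshold`
#' @examples
#' scoreTSS(c(0.1, 0.8, 0.3, 0.6), c(0, 1, 0, 1))$tss # 1
#' @export
scoreTSS <- function(predicted, labels) {
  checkPairs(labels, predicted)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("TSS undefined: labels contain a single class")
  u <- sort(unique(predicted))
  cand <- u[1L]
  if (length(u) > 1L)
    cand <- sort(unique(c(u[1L], (u[-1L] + u[-length(u)]) / 2, u[length(u)])))
  best <- -Inf
  bestThr <- cand[1L]
  for (thr in cand) {
    pos <- predicted >= thr
    sens <- sum(pos & labels == 1L) / npos
    spec <- sum(!pos & labels == 0L) / nneg
    tss <- sens + spec - 1
    if (tss > best + 1e-12) {
      best <- tss
      bestThr <- thr
    }
  }
  list(tss = best, threshold = bestThr)
}
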