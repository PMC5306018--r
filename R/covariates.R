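## Collinearity pruning of covariate stacks: within every pair of continuous
## layers whose pairwise Pearson |r| exceeds the threshold, the
## lower-priority layer is removed, greedily resolving the most collinear
## pair first. Categorical layers never enter the correlation computation.

#' Prune collinear continuous layers from a covariate stack
#'
#' Pearson correlations are computed over cells with complete data in both
#' layers. Removal is greedy by descending `|r|`: while any retained pair
#' has `|r|` strictly greater than the threshold, the pair with the largest
#' `|r|` is resolved by dropping its lower-priority member (larger priority
#' rank). Constant (zero-variance) layers are excluded from the correlation
#' computation with a warning and passed through. The operation is
#' idempotent, and no retained continuous pair violates the threshold.
#'
#' @param stack a [GridStack-class] with priority ranks
#' @param threshold strict pairwise correlation bound (default 0.7; a pair
#'   at exactly the threshold is retained)
#' @return the pruned [GridStack-class], with a `pruneReport` attribute:
#'   data.frame of (kept, removed, r) rows in removal order
#' @export
pruneCorrelated <- function(stack, threshold = 0.7) {
  kinds <- layerKind(stack)
  prio <- layerPriority(stack)
  contNames <- names(kinds)[kinds == "continuous"]
  if (length(contNames) < 1L)
    stop("stack has no continuous layer")
  vals <- sapply(contNames, function(nm) as.vector(getLayer(stack, nm)))
  sds <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  constant <- contNames[is.na(sds) | sds == 0]
  if (length(constant))
    warning("constant layer(s) excluded from correlation pruning: ",
            paste(constant, collapse = ", "))
  active <- setdiff(contNames, constant)
  report <- data.frame(kept = character(), removed = character(),
                       r = numeric(), stringsAsFactors = FALSE)
  if (length(active) >= 2L) {
    cm <- stats::cor(vals[, active, drop = FALSE],
                     use = "pairwise.complete.obs")
    repeat {
      acm <- abs(cm)
      diag(acm) <- 0
      if (all(acm <= threshold, na.rm = TRUE)) break
      worst <- which(acm == max(acm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      a <- rownames(acm)[worst[1L]]
      b <- colnames(acm)[worst[2L]]
      drop <- if (prio[[a]] <= prio[[b]]) b else a
      keep <- setdiff(c(a, b), drop)
      report <- rbind(report, data.frame(kept = keep, removed = drop,
                                         r = cm[a, b]))
      idx <- rownames(cm) != drop
      cm <- cm[idx, idx, drop = FALSE]
      if (nrow(cm) < 2L) break
    }
    active <- rownames(cm)
  }
  keepNames <- layerNames(stack)[layerNames(stack) %in%
                                   c(active, constant) |
                                   kinds == "categorical"]
  out <- subsetLayers(stack, keepNames)
  attr(out, "pruneReport") <- report
  out
}

#' Write a pruning report as CSV
#'
#' @param stack output of [pruneCorrelated()]
#' @param path output CSV path
#' @export
writePruneReport <- function(stack, path) {
  report <- attr(stack, "pruneReport")
  if (is.null(report))
    stop("stack carries no pruneReport attribute")
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
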