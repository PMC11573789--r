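# Independent oracles used across the suite. These deliberately re-derive
# quantities by direct enumeration, never by calling the code paths they
# check.

# Brute-force recount of confusion counts and metrics at every candidate
# threshold, plus both curve areas accumulated point by point in
# most-to-least-stringent threshold order.
oracleSweep <- function(scores, labels) {
  keep <- labels %in% c("pos", "neg")
  s <- scores[keep]
  l <- labels[keep]
  thr <- c(-Inf, sort(unique(s)), Inf)
  rows <- t(vapply(thr, function(t) {
    pred <- s >= t
    TP <- sum(pred & l == "pos"); FP <- sum(pred & l == "neg")
    FN <- sum(!pred & l == "pos"); TN <- sum(!pred & l == "neg")
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    mcc <- if (den > 0) (TP * TN - FP * FN) / den else 0
    c(t, TP, FP, TN, FN, sens, prec, spec, mcc)
  }, numeric(9)))
  tab <- as.data.frame(rows)
  colnames(tab) <- c("threshold", "TP", "FP", "TN", "FN", "sensitivity",
                     "precision", "specificity", "mcc")
  # walk thresholds from most to least stringent
  ord <- order(tab$threshold, decreasing = TRUE)
  fpr <- (1 - tab$specificity)[ord]
  tpr <- tab$sensitivity[ord]
  auroc <- 0
  for (i in seq_len(length(ord) - 1))
    auroc <- auroc + (fpr[i + 1] - fpr[i]) * (tpr[i] + tpr[i + 1]) / 2
  nonEmpty <- ord[(tab$TP + tab$FP)[ord] > 0]
  rec <- tab$sensitivity[nonEmpty]
  prc <- tab$precision[nonEmpty]
  if (rec[1] > 0) { rec <- c(0, rec); prc <- c(prc[1], prc) }
  aupr <- 0
  for (i in seq_len(length(rec) - 1))
    aupr <- aupr + (rec[i + 1] - rec[i]) * (prc[i] + prc[i + 1]) / 2
  list(table = tab, auroc = auroc, aupr = aupr)
}

# Rank-statistic AUROC (Mann-Whitney with midranks for ties).
oracleAurocRank <- function(scores, labels) {
  keep <- labels %in% c("pos", "neg")
  s <- scores[keep]; l <- labels[keep]
  r <- rank(s)
  np <- sum(l == "pos"); nn <- sum(l == "neg")
  (sum(r[l == "pos"]) - np * (np + 1) / 2) / (np * nn)
}

# Exhaustive threshold selection: evaluate the combined MCC at every
# candidate threshold of every curve by direct recount.
oracleSelect <- function(scoreSets, labelSets, combine = mean) {
  thr <- sort(unique(unlist(c(lapply(scoreSets, function(s)
    c(-Inf, sort(unique(s)), Inf))))))
  best <- -Inf; bestT <- NA_real_
  for (t in thr) {
    vals <- mapply(function(s, l) {
      pred <- s >= t
      TP <- sum(pred & l == "pos"); FP <- sum(pred & l == "neg")
      FN <- sum(!pred & l == "pos"); TN <- sum(!pred & l == "neg")
      den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
      if (den > 0) (TP * TN - FP * FN) / den else 0
    }, scoreSets, labelSets)
    v <- combine(vals)
    if (v >= best) { best <- v; bestT <- t }   # ties toward higher threshold
  }
  bestT
}

# Monte-Carlo permutation p-value for a two-sample mean difference.
oraclePermutationP <- function(x, y, n = 4000) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0
  for (i in seq_len(n)) {
    idx <- sample.int(length(pool), nx)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n + 1)
}

# Transitive ancestor closure of a child->parent edge list by iterated
# expansion (independent of the package's igraph-based reachability).
oracleAncestors <- function(child, parent, term) {
  anc <- term
  repeat {
    more <- unique(parent[child %in% anc])
    new <- setdiff(more, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}
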