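# Benchmarking a score against reference labels: confusion counts across all
# candidate thresholds, the four classification metrics, ROC / PR curves
# with trapezoid areas, MCC-optimal threshold selection, and final calls.
#
# Conventions: a pair scores positive when score >= threshold (ties
# inclusive); MCC is defined as 0 whenever its denominator vanishes;
# precision is undefined (NA) when nothing is called positive.

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN); Precision = TP / (TP + FP);
#' Specificity = TN / (TN + FP);
#' MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' with MCC = 0 at degenerate margins and precision \code{NA} when
#' TP + FP = 0. Vectorized over counts.
#'
#' @param TP,FP,TN,FN nonnegative integer vectors.
#' @return data.frame with columns \code{sensitivity, precision,
#'   specificity, mcc}.
#' @export
#' @examples
#' metricsFromCounts(TP = 22, FP = 0, TN = 205, FN = 13)
metricsFromCounts <- function(TP, FP, TN, FN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  if (any(c(TP, FP, TN, FN) < 0)) .stopf("confusion counts must be >= 0")
  sens <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  prec <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  spec <- ifelse(TN + FP > 0, TN / (TN + FP), NA_real_)
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- ifelse(denom > 0, (TP * TN - FP * FN) / denom, 0)
  data.frame(sensitivity = sens, precision = prec, specificity = spec,
             mcc = mcc)
}

# Trapezoid area along an ordered point path (x weakly monotone; vertical
# segments contribute nothing).
.trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sweep classification thresholds over a score
#'
#' Computes confusion counts and the four metrics at every candidate
#' threshold (the sorted unique scores plus -Inf and +Inf), along with the
#' area under the ROC curve (sensitivity vs. 1 - specificity) and under the
#' precision-recall curve, both by the trapezoid rule. Unlabeled pairs are
#' ignored for counting. The PR curve starts at recall 0 with the precision
#' of the most stringent non-empty call (no further interpolation).
#'
#' @param scores numeric vector of classifier scores (finite).
#' @param labels character vector aligned with \code{scores}; entries
#'   \code{"pos"}, \code{"neg"}, or anything else for unlabeled.
#' @return a \code{\linkS4class{MetricCurve}}.
#' @export
#' @examples
#' sweepThresholds(c(3, 2.5, 1, 0.2, -1), c("pos", "pos", "neg", "pos", "neg"))
sweepThresholds <- function(scores, labels) {
  if (length(scores) != length(labels))
    .stopf("scores and labels must align")
  keep <- labels %in% c("pos", "neg") & is.finite(scores)
  s <- scores[keep]
  l <- labels[keep]
  nPos <- sum(l == "pos")
  nNeg <- sum(l == "neg")
  if (nPos == 0L || nNeg == 0L)
    .stopf("need at least one positive and one negative label (got %d/%d)",
           nPos, nNeg)
  us <- sort(unique(s))
  posAt <- tabulate(match(s[l == "pos"], us), length(us))
  negAt <- tabulate(match(s[l == "neg"], us), length(us))
  # counts at threshold t = us[i]: positives score >= t (ties inclusive)
  TP <- rev(cumsum(rev(posAt)))
  FP <- rev(cumsum(rev(negAt)))
  thr <- c(-Inf, us, Inf)
  TP <- c(nPos, TP, 0)
  FP <- c(nNeg, FP, 0)
  FN <- nPos - TP
  TN <- nNeg - FP
  met <- metricsFromCounts(TP, FP, TN, FN)
  tab <- cbind(data.frame(threshold = thr, TP = TP, FP = FP, TN = TN,
                          FN = FN), met)
  # both curves are traversed from the most to the least stringent threshold
  o <- order(thr, decreasing = TRUE)
  roc <- .trapezoid((1 - met$specificity)[o], met$sensitivity[o])
  def <- o[TP[o] + FP[o] > 0]
  rec <- met$sensitivity[def]
  prec <- met$precision[def]
  if (rec[1] > 0) {          # anchor at recall 0 with the first precision
    rec <- c(0, rec)
    prec <- c(prec[1], prec)
  }
  pr <- .trapezoid(rec, prec)
  new("MetricCurve", table = tab, auroc = roc, aupr = pr,
      scores = s, labels = l)
}

#' Select the MCC-optimal threshold across classifications
#'
#' Evaluates every curve's MCC on the union of all candidate thresholds
#' (recounting from the stored scores and labels, so curves built on
#' different score grids are comparable) and returns the threshold
#' maximizing the mean MCC across curves. Ties are broken toward the higher
#' (more stringent) threshold. \code{combine = "min"} optimizes the worst
#' curve instead of the mean.
#'
#' @param curves a \code{MetricCurve} or list of them.
#' @param combine \code{"mean"} (default) or \code{"min"}.
#' @return the selected threshold (numeric scalar).
#' @export
selectThreshold <- function(curves, combine = c("mean", "min")) {
  combine <- match.arg(combine)
  if (is(curves, "MetricCurve")) curves <- list(curves)
  if (!length(curves)) .stopf("empty curve list")
  thr <- sort(unique(unlist(lapply(curves, function(cv)
    cv@table$threshold))))
  mccAt <- vapply(curves, function(cv) {
    pos <- cv@labels == "pos"
    vapply(thr, function(t) {
      call <- cv@scores >= t
      metricsFromCounts(sum(call & pos), sum(call & !pos),
                        sum(!call & !pos), sum(!call & pos))$mcc
    }, numeric(1))
  }, numeric(length(thr)))
  mccAt <- matrix(mccAt, nrow = length(thr))
  comb <- if (combine == "mean") rowMeans(mccAt) else
    apply(mccAt, 1, min)
  best <- which(comb == max(comb))
  thr[max(best)]
}

#' Classify pairs at a threshold with a significance gate
#'
#' A pair is called positive when its score reaches the threshold and, when
#' a p-value is available, that p-value is below \code{alpha}. With
#' \code{alpha >= 1} the significance gate is disabled and the call reduces
#' to pure thresholding. Missing p-values pass the gate by default
#' (\code{missingP = "pass"}); set \code{missingP = "fail"} to require one.
#'
#' @param scores numeric vector (names propagate to the result).
#' @param threshold numeric scalar.
#' @param pValues optional numeric vector aligned with \code{scores}.
#' @param alpha significance level in (0, 1].
#' @param missingP policy for missing p-values: \code{"pass"} or
#'   \code{"fail"}.
#' @return character vector, \code{"positive"} / \code{"negative"}.
#' @export
classifyAt <- function(scores, threshold, pValues = NULL, alpha = 0.05,
                       missingP = c("pass", "fail")) {
  missingP <- match.arg(missingP)
  if (alpha <= 0 || alpha > 1) .stopf("alpha must lie in (0, 1]")
  call <- scores >= threshold
  if (!is.null(pValues) && alpha < 1) {
    gate <- ifelse(is.na(pValues), missingP == "pass", pValues < alpha)
    call <- call & gate
  }
  out <- ifelse(call, "positive", "negative")
  names(out) <- names(scores)
  out
}
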