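# Ratiometric interaction scores. Raw luminescence confounds true
# interaction with abundance-dependent reporter-fragment self-association;
# dividing a pair's signal by the signal of matched control pairs (same
# protein, different partner) cancels the abundance term. All ratios are
# computed as differences in log2 space.
#
# Two modes:
#  * shared_partner: control = the maximum signal among random pairs sharing
#    the bait or the prey of the scored pair (reference-set benchmarking).
#  * control_bait: control = the same prey measured with one or several
#    control baits, aggregated by max (systematic screens).

#' Welch-test significance of a pair against its controls
#'
#' Two-sided Welch unequal-variance t-test on log2 replicate values. With
#' fewer than two replicates on either side the p-value is reported missing
#' (\code{NA}), never 1. Degenerate zero-variance cases return 1 when the
#' means agree and 0 otherwise.
#'
#' @param pairValues numeric vector of the pair's log2 replicate values.
#' @param controlValues numeric vector of pooled control log2 replicate
#'   values.
#' @return p-value in [0, 1], or \code{NA}.
#' @export
#' @examples
#' ratioSignificance(c(5, 5.1, 4.9), c(0.1, -0.2, 0))
ratioSignificance <- function(pairValues, controlValues) {
  x <- pairValues[is.finite(pairValues)]
  y <- controlValues[is.finite(controlValues)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Rows of a PairSignalSet for one bait, as plain pieces.
.baitSlice <- function(x, bait) {
  sel <- rowData(x)$bait == bait
  list(prey = rowData(x)$prey[sel],
       mean = rowData(x)$mean_log2[sel],
       strain = rownames(x)[sel],
       censored = rowData(x)$below_detection_frac[sel] >= 1,
       values = signalMatrix(x)[sel, , drop = FALSE])
}

#' Shared-partner ratiometric score
#'
#' For each scored pair, the control is the maximum normalized log2 signal
#' among random pairs that contain either the bait or the prey of the scored
#' pair; the score is the pair's mean log2 signal minus that control.
#' Pairs listed in \code{exclusions} never serve as controls but are still
#' scored (use this for random pairs later found to produce specific signal).
#' Scored pairs with no qualifying control are omitted with a warning naming
#' them. Significance compares the pair's replicates against those of the
#' maximal control strain (Welch test).
#'
#' @param pairs \code{PairSignalSet} of scored pairs.
#' @param randomSet \code{PairSignalSet} of random (likely non-interacting)
#'   pairs drawn from the same protein set.
#' @param exclusions character vector of pair ids (\code{\link{pairKey}})
#'   excluded from serving as controls.
#' @return data.frame with columns \code{bait, prey, pair_id, log2_ratio,
#'   p_value, mode, n_controls, control_ids}.
#' @export
sharedPartnerRatio <- function(pairs, randomSet, exclusions = character()) {
  rdP <- rowData(pairs)
  rdR <- rowData(randomSet)
  rKey <- pairKey(rdR$bait, rdR$prey)
  usable <- !(rKey %in% exclusions)
  valsR <- signalMatrix(randomSet)
  out <- vector("list", nrow(pairs))
  skipped <- character()
  for (i in seq_len(nrow(pairs))) {
    b <- rdP$bait[i]; p <- rdP$prey[i]
    key <- pairKey(b, p)
    qual <- usable & (rdR$bait %in% c(b, p) | rdR$prey %in% c(b, p)) &
      rKey != key
    if (!any(qual)) {
      skipped <- c(skipped, key)
      next
    }
    ctrlMeans <- rdR$mean_log2[qual]
    j <- which(qual)[which.max(ctrlMeans)]
    out[[i]] <- data.frame(
      bait = b, prey = p, pair_id = key,
      log2_ratio = rdP$mean_log2[i] - max(ctrlMeans),
      p_value = ratioSignificance(signalMatrix(pairs)[i, ],
                                  valsR[j, ]),
      mode = "shared_partner",
      n_controls = sum(qual),
      control_ids = rownames(randomSet)[j],
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    .warnf("no qualifying shared-partner control for: %s",
           paste(skipped, collapse = ", "))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Control-bait ratiometric score
#'
#' Scores every prey measured with the target bait against the same prey
#' measured with one or more control baits. The control value is the maximum
#' of the control-bait signals for that prey (the most conservative
#' aggregation; \code{aggregate = "mean"} averages instead). Preys absent
#' from every control are omitted. Pairs in which the target and all used
#' controls sit at the detection limit are flagged uninformative. Known
#' partners of the target must not be offered as control baits (pass a
#' control list that excludes them).
#'
#' @param signals \code{PairSignalSet} holding the target and control baits.
#' @param targetBait bait id to score.
#' @param controlBaits nonempty character vector of control bait ids.
#' @param aggregate \code{"max"} (default) or \code{"mean"} over control
#'   baits.
#' @return data.frame with columns \code{bait, prey, pair_id, log2_ratio,
#'   p_value, mode, n_controls, control_ids, uninformative}.
#' @export
#' @examples
#' sim <- simulateScreen(exampleUniverse(), exampleNetwork(),
#'                       screenDesign(baits = c("P01", "P06"),
#'                                    preys = sprintf("P%02d", 1:12),
#'                                    replicates = 3, seed = 3))
#' ps <- normalizeScreen(sim@measurements, sim@strainMap)
#' head(controlBaitRatio(ps, "P01", "P06"))
controlBaitRatio <- function(signals, targetBait, controlBaits,
                             aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(controlBaits)) .stopf("empty control bait list")
  if (targetBait %in% controlBaits)
    .stopf("target bait cannot serve as its own control")
  tgt <- .baitSlice(signals, targetBait)
  if (!length(tgt$prey))
    .stopf("bait '%s' not present in the signal set", targetBait)
  ctl <- lapply(controlBaits, function(b) .baitSlice(signals, b))
  names(ctl) <- controlBaits
  out <- vector("list", length(tgt$prey))
  for (i in seq_along(tgt$prey)) {
    p <- tgt$prey[i]
    hits <- lapply(ctl, function(s) which(s$prey == p)[1])
    have <- !vapply(hits, is.na, logical(1))
    if (!any(have)) next
    cm <- vapply(which(have), function(k) ctl[[k]]$mean[hits[[k]]],
                 numeric(1))
    ctrlVal <- if (aggregate == "max") max(cm) else mean(cm)
    pooled <- unlist(lapply(which(have), function(k)
      ctl[[k]]$values[hits[[k]], ]))
    cens <- vapply(which(have), function(k) ctl[[k]]$censored[hits[[k]]],
                   logical(1))
    out[[i]] <- data.frame(
      bait = targetBait, prey = p, pair_id = pairKey(targetBait, p),
      log2_ratio = tgt$mean[i] - ctrlVal,
      p_value = ratioSignificance(tgt$values[i, ], pooled),
      mode = "control_bait",
      n_controls = sum(have),
      control_ids = paste(names(ctl)[have], collapse = ","),
      uninformative = isTRUE(tgt$censored[i]) && all(cens),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    .stopf("no prey of bait '%s' is measured with any control bait",
           targetBait)
  rownames(res) <- NULL
  res
}

#' Mutant-versus-wild-type differential interaction profile
#'
#' For a prey panel measured with a wild-type bait and one or more mutant
#' baits, computes per (mutant, prey) the log2 fold change (mutant mean minus
#' wild-type mean) with Welch-test significance. Preys missing in the
#' wild-type set are dropped with a warning; preys missing in a given mutant
#' yield \code{NA} in that column.
#'
#' @param wt \code{PairSignalSet} of the wild-type bait (a single bait).
#' @param mutants named list of \code{PairSignalSet}s, one per mutant.
#' @return list with matrices \code{log2fc} and \code{p_value}
#'   (preys x mutants).
#' @export
differentialProfile <- function(wt, mutants) {
  if (is.null(names(mutants)) || any(!nzchar(names(mutants))))
    .stopf("mutants must be a named list")
  preysWT <- rowData(wt)$prey
  allPreys <- unique(unlist(lapply(mutants, function(m) rowData(m)$prey)))
  missing <- setdiff(allPreys, preysWT)
  if (length(missing))
    .warnf("dropping %d prey(s) missing from the wild-type panel: %s",
           length(missing), paste(utils::head(missing, 5), collapse = ", "))
  preys <- intersect(preysWT, allPreys)
  lfc <- pv <- matrix(NA_real_, length(preys), length(mutants),
                      dimnames = list(preys, names(mutants)))
  wtVals <- signalMatrix(wt)
  wtMean <- rowData(wt)$mean_log2
  for (m in names(mutants)) {
    rdM <- rowData(mutants[[m]])
    mv <- signalMatrix(mutants[[m]])
    for (p in preys) {
      iw <- which(preysWT == p)[1]
      im <- which(rdM$prey == p)[1]
      if (is.na(im)) next
      lfc[p, m] <- rdM$mean_log2[im] - wtMean[iw]
      pv[p, m] <- ratioSignificance(mv[im, ], wtVals[iw, ])
    }
  }
  list(log2fc = lfc, p_value = pv)
}

#' Hierarchically cluster differential interaction profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' log2 fold-change matrix, over rows (preys) and columns (mutants). Missing
#' entries are imputed to 0 (no change) and flagged. With fewer than two rows
#' the row dendrogram is trivial (\code{NULL}).
#'
#' @param log2fc numeric matrix, preys x mutants.
#' @return list with elements \code{rows}, \code{cols} (hclust or NULL),
#'   \code{row_order}, \code{col_order} (leaf orders as labels),
#'   \code{imputed} (logical matrix), \code{newick_rows}, \code{newick_cols}
#'   (Newick strings or NA).
#' @export
clusterProfiles <- function(log2fc) {
  imputed <- !is.finite(log2fc)
  m <- log2fc
  m[imputed] <- 0
  clusterDim <- function(mm) {
    if (nrow(mm) < 2L) return(NULL)
    stats::hclust(stats::dist(mm, method = "euclidean"), method = "average")
  }
  hr <- clusterDim(m)
  hc <- clusterDim(t(m))
  toNewick <- function(h) {
    if (is.null(h) || length(h$labels) < 2L) return(NA_character_)
    ape::write.tree(ape::as.phylo(h))
  }
  list(rows = hr, cols = hc,
       row_order = if (is.null(hr)) rownames(m) else hr$labels[hr$order],
       col_order = if (is.null(hc)) colnames(m) else hc$labels[hc$order],
       imputed = imputed,
       newick_rows = toNewick(hr), newick_cols = toNewick(hc))
}
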