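#' Accessors for PairSignalSet
#'
#' \code{signalMatrix} returns the strains x replicates matrix of plate-
#' normalized log2 signals; \code{meanLog2} the per-strain replicate mean
#' (named by strain id); \code{belowDetection} the logical censoring matrix;
#' \code{pairInfo} the strain annotation (bait, prey, summaries) as a
#' \code{DataFrame}.
#'
#' @param x a \code{PairSignalSet}.
#' @return See individual descriptions.
#' @name PairSignalSet-accessors
#' @aliases signalMatrix meanLog2 belowDetection pairInfo
#' @examples
#' sim <- simulateScreen(exampleUniverse(12), exampleNetwork(),
#'                       screenDesign(baits = "P01", preys = sprintf("P%02d", 2:12),
#'                                    replicates = 2, seed = 1))
#' ps <- normalizeScreen(sim@measurements, sim@strainMap)
#' head(meanLog2(ps))
NULL

#' @rdname PairSignalSet-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname PairSignalSet-accessors
#' @export
setGeneric("meanLog2", function(x) standardGeneric("meanLog2"))

#' @rdname PairSignalSet-accessors
#' @export
setGeneric("belowDetection", function(x) standardGeneric("belowDetection"))

#' @rdname PairSignalSet-accessors
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' @rdname PairSignalSet-accessors
setMethod("signalMatrix", "PairSignalSet", function(x)
  SummarizedExperiment::assay(x, "log2signal"))

#' @rdname PairSignalSet-accessors
setMethod("meanLog2", "PairSignalSet", function(x) {
  out <- rowData(x)$mean_log2
  names(out) <- rownames(x)
  out
})

#' @rdname PairSignalSet-accessors
setMethod("belowDetection", "PairSignalSet", function(x)
  SummarizedExperiment::assay(x, "belowDetection"))

#' @rdname PairSignalSet-accessors
setMethod("pairInfo", "PairSignalSet", function(x) rowData(x))

#' Accessors for MetricCurve
#'
#' \code{curveTable} returns the per-threshold confusion counts and metrics;
#' \code{auroc} and \code{aupr} the areas under the ROC and precision-recall
#' curves.
#'
#' @param x a \code{MetricCurve}.
#' @return \code{curveTable}: a data.frame; \code{auroc}, \code{aupr}:
#'   numeric scalars.
#' @name MetricCurve-accessors
#' @aliases curveTable auroc aupr
NULL

#' @rdname MetricCurve-accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname MetricCurve-accessors
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))

#' @rdname MetricCurve-accessors
#' @export
setGeneric("aupr", function(x) standardGeneric("aupr"))

#' @rdname MetricCurve-accessors
setMethod("curveTable", "MetricCurve", function(x) x@table)

#' @rdname MetricCurve-accessors
setMethod("auroc", "MetricCurve", function(x) x@auroc)

#' @rdname MetricCurve-accessors
setMethod("aupr", "MetricCurve", function(x) x@aupr)

#' Accessors for ReferenceSet
#'
#' @param x a \code{ReferenceSet}.
#' @return \code{positives}, \code{negatives}: character vectors of prey ids;
#'   \code{evidenceCounts}: named integer vector.
#' @name ReferenceSet-accessors
#' @aliases positives negatives evidenceCounts
NULL

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("negatives", function(x) standardGeneric("negatives"))

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("evidenceCounts", function(x) standardGeneric("evidenceCounts"))

#' @rdname ReferenceSet-accessors
setMethod("positives", "ReferenceSet", function(x) x@positives)

#' @rdname ReferenceSet-accessors
setMethod("negatives", "ReferenceSet", function(x) x@negatives)

#' @rdname ReferenceSet-accessors
setMethod("evidenceCounts", "ReferenceSet", function(x) x@evidenceCounts)
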