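#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# Channels a plate reader emits in this workflow.
.CHANNELS <- c("luminescence", "fluorescence", "od600")

# Sentinel strain id for medium-only wells.
BLANK_SENTINEL <- "BLANK"

#' ScreenDesign: layout and generative parameters of a simulated plate screen
#'
#' A \code{ScreenDesign} bundles everything needed to turn a protein universe
#' and a true interaction network into raw plate readings: which baits are
#' crossed against which preys, how many replicate plate reads are taken, the
#' plate format, per-plate-read linear effects in log2 space, the luminometer
#' detection limit, replicate noise, and the coefficients of the latent signal
#' model (see \code{\link{simulateScreen}}).
#'
#' @slot baits character vector of bait protein ids.
#' @slot preys character vector of prey protein ids.
#' @slot replicates integer, number of replicate plate reads (>= 1).
#' @slot plateFormat integer, 96 or 384 wells.
#' @slot blanksPerPlate integer, medium-only wells reserved per plate.
#' @slot plateEffects data.frame with columns \code{plate_id},
#'   \code{replicate_id}, \code{slope}, \code{offset}; the linear distortion
#'   applied to each plate read in log2 space. Empty means identity.
#' @slot detectionLimit positive numeric; luminometer floor in signal units.
#' @slot noiseSd nonnegative numeric; replicate noise SD in log2 units.
#' @slot kInteraction nonnegative numeric; luminescence per complex formed by
#'   a true interaction.
#' @slot kSelf nonnegative numeric; mass-action coefficient of reporter
#'   fragment self-association background.
#' @slot colocalizationOther numeric in [0, 1]; colocalization factor for
#'   pairs in different compartments (same compartment counts 1).
#' @slot assay character, \code{"NanoBiT"} (pairwise complementation) or
#'   \code{"NanoLuc"} (full-length reporter, abundance readout).
#' @slot densityChannel character, \code{"fluorescence"} or \code{"od600"}.
#' @slot densityLevel positive numeric; cell density signal above background.
#' @slot backgroundLevel nonnegative numeric; instrument background counts.
#' @slot backgroundSd nonnegative numeric; SD of blank-well readings.
#' @slot seed integer seed for the single RNG stream.
#'
#' @exportClass ScreenDesign
setClass("ScreenDesign",
  representation(
    baits = "character",
    preys = "character",
    replicates = "integer",
    plateFormat = "integer",
    blanksPerPlate = "integer",
    plateEffects = "data.frame",
    detectionLimit = "numeric",
    noiseSd = "numeric",
    kInteraction = "numeric",
    kSelf = "numeric",
    colocalizationOther = "numeric",
    assay = "character",
    densityChannel = "character",
    densityLevel = "numeric",
    backgroundLevel = "numeric",
    backgroundSd = "numeric",
    seed = "integer"
  )
)

setValidity("ScreenDesign", function(object) {
  msg <- character()
  if (object@replicates < 1L)
    msg <- c(msg, "replicates must be >= 1")
  if (!object@plateFormat %in% c(96L, 384L))
    msg <- c(msg, "plateFormat must be 96 or 384")
  if (object@detectionLimit <= 0)
    msg <- c(msg, "detectionLimit must be positive")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be nonnegative")
  if (object@kSelf < 0 || object@kInteraction < 0)
    msg <- c(msg, "signal coefficients must be nonnegative")
  if (object@colocalizationOther < 0 || object@colocalizationOther > 1)
    msg <- c(msg, "colocalizationOther must lie in [0, 1]")
  if (!object@assay %in% c("NanoBiT", "NanoLuc"))
    msg <- c(msg, "assay must be 'NanoBiT' or 'NanoLuc'")
  if (nrow(object@plateEffects) &&
      !all(c("plate_id", "replicate_id", "slope", "offset") %in%
           colnames(object@plateEffects)))
    msg <- c(msg, "plateEffects needs plate_id, replicate_id, slope, offset")
  if (nrow(object@plateEffects) &&
      !all(is.finite(object@plateEffects$slope) &
           is.finite(object@plateEffects$offset)))
    msg <- c(msg, "plateEffects must be finite")
  if (length(msg)) msg else TRUE
})

#' ScreenSimulation: a simulated plate screen with its ground truth
#'
#' Returned by \code{\link{simulateScreen}}. Holds the long-format measurement
#' table, the strain map linking wells to bait-prey pairs, the latent
#' (noise-free, effect-free) log2 signals, and the design that generated them.
#'
#' @slot measurements data.frame of raw well readings (see
#'   \code{\link{readMeasurements}} for the column contract).
#' @slot strainMap data.frame mapping strain ids to bait/prey/tag/ploidy.
#' @slot latentLog2 named numeric; closed-form latent log2 signal per strain.
#' @slot design the generating \code{ScreenDesign}.
#'
#' @exportClass ScreenSimulation
setClass("ScreenSimulation",
  representation(
    measurements = "data.frame",
    strainMap = "data.frame",
    latentLog2 = "numeric",
    design = "ScreenDesign"
  )
)

setMethod("show", "ScreenSimulation", function(object) {
  d <- object@design
  cat("ScreenSimulation (", d@assay, ")\n", sep = "")
  cat("  strains: ", nrow(object@strainMap), " on ",
      length(unique(object@measurements$plate_id)), " plate(s) x ",
      d@replicates, " replicate(s)\n", sep = "")
  cat("  records: ", nrow(object@measurements), "\n", sep = "")
})

#' PairSignalSet: normalized per-strain log2 signals across replicates
#'
#' Thin extension of \code{SummarizedExperiment}: rows are strains (bait-prey
#' pairs), columns are replicates. The \code{"log2signal"} assay holds plate-
#' normalized log2 luminescence; the \code{"belowDetection"} assay marks
#' replicates censored at the luminometer detection limit. \code{rowData}
#' carries \code{bait}, \code{prey}, \code{mean_log2},
#' \code{below_detection_frac} and \code{detection_limit_log2};
#' \code{metadata} carries replicate-correlation QC and per-plate fits.
#'
#' @exportClass PairSignalSet
setClass("PairSignalSet", contains = "SummarizedExperiment")

setValidity("PairSignalSet", function(object) {
  msg <- character()
  if (!all(c("log2signal", "belowDetection") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'log2signal' and 'belowDetection' are required")
  need <- c("bait", "prey", "mean_log2", "below_detection_frac",
            "detection_limit_log2")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairSignalSet", function(object) {
  cat("PairSignalSet with ", nrow(object), " strain(s) x ", ncol(object),
      " replicate(s)\n", sep = "")
  bd <- rowData(object)$below_detection_frac
  cat("  fully censored strains: ", sum(bd >= 1), "\n", sep = "")
  qc <- metadata(object)$replicate_correlation
  if (!is.null(qc) && nrow(qc) > 1) {
    r <- qc[upper.tri(qc)]
    cat("  inter-replicate Pearson R: ",
        paste(format(range(r), digits = 3), collapse = " - "), "\n", sep = "")
  }
})

#' MetricCurve: classifier metrics across a threshold sweep
#'
#' Produced by \code{\link{sweepThresholds}}. Stores confusion counts and the
#' four classification metrics at every candidate threshold, the areas under
#' the ROC and precision-recall curves, and the scores/labels the sweep was
#' computed from (so that \code{\link{selectThreshold}} can re-evaluate the
#' curve on a shared threshold grid).
#'
#' @slot table data.frame with columns \code{threshold, TP, FP, TN, FN,
#'   sensitivity, precision, specificity, mcc}.
#' @slot auroc numeric in [0, 1].
#' @slot aupr numeric in [0, 1].
#' @slot scores named numeric vector of classifier scores.
#' @slot labels character vector ("pos"/"neg") aligned with \code{scores}.
#'
#' @exportClass MetricCurve
setClass("MetricCurve",
  representation(
    table = "data.frame",
    auroc = "numeric",
    aupr = "numeric",
    scores = "numeric",
    labels = "character"
  )
)

setValidity("MetricCurve", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("threshold", "TP", "FP", "TN", "FN", "sensitivity", "precision",
            "specificity", "mcc")
  if (!all(need %in% colnames(tab)))
    msg <- c(msg, "table is missing metric columns")
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must align")
  ok <- stats::complete.cases(tab[, c("sensitivity", "specificity")])
  if (any(tab$sensitivity[ok] < 0 | tab$sensitivity[ok] > 1))
    msg <- c(msg, "sensitivity out of [0, 1]")
  if (any(abs(tab$mcc) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "MCC out of [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetricCurve", function(object) {
  cat("MetricCurve over ", nrow(object@table), " thresholds (",
      sum(object@labels == "pos"), " pos / ", sum(object@labels == "neg"),
      " neg)\n", sep = "")
  cat("  AUROC = ", format(object@auroc, digits = 4),
      ", AUPR = ", format(object@aupr, digits = 4), "\n", sep = "")
  i <- which.max(object@table$mcc)
  cat("  max MCC = ", format(object@table$mcc[i], digits = 4),
      " at threshold ", format(object@table$threshold[i], digits = 4),
      "\n", sep = "")
})

#' Ontology: a directed acyclic graph of controlled-vocabulary terms
#'
#' Child-to-parent edges over term ids, as used for molecular-interaction
#' detection methods and Gene Ontology annotation filtering. Construct with
#' \code{\link{readOntology}} or \code{\link{ontologyFromEdges}}.
#'
#' @slot terms character vector of all term ids.
#' @slot graph an \code{igraph} with edges child -> parent.
#'
#' @exportClass Ontology
setClass("Ontology",
  representation(terms = "character", graph = "ANY")
)

setValidity("Ontology", function(object) {
  if (!igraph::is_dag(object@graph))
    return("ontology term graph must be acyclic")
  TRUE
})

setMethod("show", "Ontology", function(object) {
  cat("Ontology with ", length(object@terms), " terms and ",
      igraph::ecount(object@graph), " child->parent edges\n", sep = "")
})

#' ReferenceSet: positive and negative reference labels for one bait
#'
#' Built by \code{\link{buildReference}} from deduplicated interaction
#' evidence. Positives are preys supported by at least \code{minEvidence}
#' non-redundant experimental observations with the bait; negatives are preys
#' with no recorded evidence that also escape the functional (GO) exclusion
#' filter; everything else is unlabeled.
#'
#' @slot bait character scalar.
#' @slot positives character vector of prey ids.
#' @slot negatives character vector of prey ids.
#' @slot evidenceCounts named integer; deduplicated evidence count per prey.
#' @slot minEvidence integer threshold used.
#'
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    bait = "character",
    positives = "character",
    negatives = "character",
    evidenceCounts = "integer",
    minEvidence = "integer"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(intersect(object@positives, object@negatives)))
    msg <- c(msg, "positives and negatives must be disjoint")
  if (object@minEvidence < 1L)
    msg <- c(msg, "minEvidence must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet for bait ", object@bait, ": ",
      length(object@positives), " positives (>= ", object@minEvidence,
      " pieces of evidence), ", length(object@negatives),
      " likely non-interactors\n", sep = "")
})
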