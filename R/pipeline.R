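# End-to-end orchestration: one config (R list or YAML file) drives
# simulate -> normalize -> score -> classify (and the differential and
# curation paths), writing every stage output plus a machine-readable run
# report. Identical config + seed give identical outputs.

.configError <- function(fmt, ...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

.dataError <- function(fmt, ...) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

.runStage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "config_error")) stop(e)
    .dataError("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Read a pipeline configuration
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      .configError("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .configError("config must be a list or a YAML path")
  if (is.null(config$mode) ||
      !config$mode %in% c("reference_set", "screen", "differential",
                          "curate"))
    .configError("config$mode must be one of reference_set/screen/differential/curate")
  config
}

# Obtain measurements + strain map + optional labels, either from files or
# from the packaged generator.
.loadScreen <- function(config, seed) {
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    prot <- sampleProteins(
      n = sc$n_proteins %||% 100L,
      meanlog = sc$abundance_meanlog %||% log(1000),
      sdlog = sc$abundance_sdlog %||% 2,
      seed = seed)
    edges <- sc$edges
    net <- if (is.null(edges)) ppiNetwork() else {
      e <- do.call(rbind, lapply(edges, function(x)
        data.frame(a = x[[1]], b = x[[2]],
                   s = as.numeric(x[[3]]), stringsAsFactors = FALSE)))
      ppiNetwork(e$a, e$b, e$s)
    }
    baits <- sc$baits %||% prot$protein_id[1]
    preys <- sc$preys %||% prot$protein_id
    design <- screenDesign(
      baits = baits, preys = preys,
      replicates = sc$replicates %||% 3L,
      noiseSd = sc$noise_sd %||% 0.25,
      kSelf = sc$k_self %||% 1e-7,
      detectionLimit = sc$detection_limit %||% 2,
      seed = seed)
    sim <- simulateScreen(prot, net, design)
    labels <- groundTruthLabels(net, design)
    list(measurements = sim@measurements, strainMap = sim@strainMap,
         labels = labels)
  } else {
    inp <- config$input
    if (is.null(inp$measurements) || is.null(inp$strain_map))
      .configError("config$input needs measurements and strain_map paths")
    labels <- NULL
    if (!is.null(inp$labels)) {
      labels <- utils::read.table(inp$labels, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
      .requireColumns(labels, c("pair_id", "label"), "labels file")
    }
    list(measurements = readMeasurements(inp$measurements),
         strainMap = readStrainMap(inp$strain_map),
         labels = labels)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.labelsFor <- function(labels, pairIds) {
  if (is.null(labels)) return(rep("unlabeled", length(pairIds)))
  lab <- labels$label[match(pairIds, labels$pair_id)]
  out <- rep("unlabeled", length(pairIds))
  out[lab %in% c("positive", "pos")] <- "pos"
  out[lab %in% c("negative", "neg")] <- "neg"
  out
}

.chooseThreshold <- function(config, curves) {
  pol <- config$threshold_policy %||% list(type = "max_mcc")
  if (identical(pol$type, "fixed")) {
    if (is.null(pol$value)) .configError("fixed threshold_policy needs value")
    as.numeric(pol$value)
  } else selectThreshold(curves)
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the stage graph for the configured mode and writes every stage
#' output plus a JSON run report into the output directory:
#' \describe{
#'   \item{screen}{normalize, control-bait ratios for the target bait, and,
#'     when labels are available, a threshold sweep, threshold selection and
#'     final calls.}
#'   \item{reference_set}{normalize, shared-partner ratios of every pair
#'     against the random (negative-labeled) pairs, threshold sweep and
#'     calls.}
#'   \item{differential}{normalize, mutant-vs-wild-type log2 fold changes
#'     with significance, and hierarchical clustering (Newick in the
#'     report).}
#'   \item{curate}{evidence filtering, ontology-aware deduplication and
#'     reference-set construction.}
#' }
#' Inputs come either from files (\code{config$input}) or from the packaged
#' generator (\code{config$simulate}). All randomness derives from
#' \code{config$seed}.
#'
#' @param config named list or YAML path; see \code{\link{readRunConfig}}.
#' @return the run report, invisibly (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% .configError("config$output_dir required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("RatioScreen")),
                 mode = config$mode, seed = seed,
                 config = config[setdiff(names(config), "output_dir")],
                 warnings = character(), outputs = character())
  wlog <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    writeTable(df, path)
    report$outputs <<- c(report$outputs, path)
  }

  withCallingHandlers(warning = wlog, {
    if (config$mode == "curate") {
      onto <- .runStage("ontology", readOntology(config$input$ontology))
      ev <- .runStage("evidence", readEvidence(config$input$evidence))
      ev <- .runStage("filter", filterPPI(ev, onto,
        root = config$ppi_root %||% "MI:0915"))
      ev <- .runStage("deduplicate", deduplicateEvidence(ev, onto))
      ann <- NULL
      if (!is.null(config$input$go_annotations)) {
        ann <- utils::read.table(config$input$go_annotations, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
      }
      goOnto <- if (!is.null(config$input$go_ontology))
        readOntology(config$input$go_ontology) else NULL
      universe <- if (!is.null(config$input$universe))
        readLines(config$input$universe) else
        unique(c(ev$protein_a, ev$protein_b))
      ref <- .runStage("reference", buildReference(
        ev, bait = config$bait, universe = universe,
        minEvidence = config$min_evidence %||% 3L,
        goAnnotations = ann,
        excludedGoTerms = config$excluded_go_terms %||% character(),
        goOntology = goOnto))
      emit(ev, "evidence_deduplicated.tsv")
      emit(data.frame(prey = c(positives(ref), negatives(ref)),
                      label = rep(c("positive", "negative"),
                                  c(length(positives(ref)),
                                    length(negatives(ref))))),
           "reference_labels.tsv")
      report$counts <- list(positives = length(positives(ref)),
                            negatives = length(negatives(ref)),
                            evidence_records = nrow(ev))
    } else {
      dat <- .runStage("load", .loadScreen(config, seed))
      ps <- .runStage("normalize",
                      normalizeScreen(dat$measurements, dat$strainMap))
      rd <- rowData(ps)
      emit(data.frame(strain_id = rownames(ps), bait = rd$bait,
                      prey = rd$prey, mean_log2 = rd$mean_log2,
                      n_replicates = rowSums(is.finite(signalMatrix(ps))),
                      below_detection_frac = rd$below_detection_frac),
           "signals.tsv")
      qc <- metadata(ps)$replicate_correlation
      report$qc <- list(
        replicate_correlation = qc,
        min_replicate_correlation = if (!is.null(qc) && nrow(qc) > 1)
          min(qc[upper.tri(qc)]) else NA)

      if (config$mode == "screen") {
        if (is.null(config$target_bait))
          .configError("screen mode needs config$target_bait")
        ctl <- config$control_baits %||%
          setdiff(unique(rd$bait), config$target_bait)
        if (!length(ctl)) .configError("no control baits available")
        ratios <- .runStage("score",
          controlBaitRatio(ps, config$target_bait, unlist(ctl)))
      } else if (config$mode == "reference_set") {
        lab0 <- .labelsFor(dat$labels, pairKey(rd$bait, rd$prey))
        if (!any(lab0 == "neg"))
          .configError("reference_set mode needs negative-labeled pairs")
        randomSet <- ps[lab0 == "neg", ]
        ratios <- .runStage("score",
          sharedPartnerRatio(ps, randomSet,
                             exclusions = unlist(config$exclusions %||%
                                                   character())))
      } else {                                    # differential
        if (is.null(config$wt_bait) || is.null(config$mutant_baits))
          .configError("differential mode needs wt_bait and mutant_baits")
        wt <- ps[rd$bait == config$wt_bait, ]
        muts <- lapply(config$mutant_baits, function(b)
          ps[rd$bait == b, ])
        names(muts) <- unlist(config$mutant_baits)
        prof <- .runStage("differential", differentialProfile(wt, muts))
        cl <- .runStage("cluster", clusterProfiles(prof$log2fc))
        emit(data.frame(prey = rownames(prof$log2fc),
                        prof$log2fc, check.names = FALSE),
             "differential_log2fc.tsv")
        emit(data.frame(prey = rownames(prof$p_value),
                        prof$p_value, check.names = FALSE),
             "differential_pvalues.tsv")
        report$clustering <- list(row_order = cl$row_order,
                                  col_order = cl$col_order,
                                  newick_rows = cl$newick_rows,
                                  newick_cols = cl$newick_cols)
        report$counts <- list(preys = nrow(prof$log2fc),
                              mutants = ncol(prof$log2fc))
        ratios <- NULL
      }

      if (!is.null(ratios)) {
        emit(ratios, "ratios.tsv")
        lab <- .labelsFor(dat$labels, ratios$pair_id)
        if (any(lab == "pos") && any(lab == "neg")) {
          curve <- .runStage("classify",
                             sweepThresholds(ratios$log2_ratio, lab))
          emit(curveTable(curve), "metric_curve.tsv")
          thr <- .chooseThreshold(config, list(curve))
          calls <- classifyAt(
            stats::setNames(ratios$log2_ratio, ratios$pair_id), thr,
            pValues = ratios$p_value,
            alpha = config$alpha %||% 0.05)
          emit(data.frame(pair_id = names(calls),
                          score = ratios$log2_ratio, call = calls),
               "calls.tsv")
          i <- which(curveTable(curve)$threshold == thr)[1]
          report$classification <- list(
            auroc = auroc(curve), aupr = aupr(curve), threshold = thr,
            counts_at_threshold = if (!is.na(i))
              as.list(curveTable(curve)[i, c("TP", "FP", "TN", "FN")])
              else NULL,
            n_positive_calls = sum(calls == "positive"))
        }
        report$counts <- c(report$counts,
                           list(pairs_scored = nrow(ratios)))
      }
    }
  })
  reportPath <- file.path(outDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  report$outputs <- c(report$outputs, reportPath)
  invisible(report)
}
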