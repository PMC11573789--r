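# Raw well readings -> per-strain normalized log2 signals.
#
# The chain is: background subtraction (per-plate blank median, with a
# detection floor at blank median + 3 robust SD), cell-density correction
# (luminescence / density, each background subtracted), log2 transform, and
# per-plate linear regression against cross-replicate medians to remove
# plate/day effects, followed by replicate aggregation with QC.

#' Subtract instrument background from plate readings
#'
#' Background is estimated per (plate, replicate, channel) as the median of
#' the medium-only (\code{"BLANK"}) wells; the detection floor is three
#' robust SDs (MAD) of the blanks above that median, so readings below it are
#' indistinguishable from instrument noise. Censored readings are set to the
#' floor (not dropped) and flagged, keeping downstream ratios computable.
#'
#' @param records long-format measurement data.frame (see
#'   \code{\link{readMeasurements}}).
#' @param background optional named numeric (by channel) or scalar constant
#'   used for plate reads that have no blank wells.
#' @param epsilon positive floor for background-subtracted values; also the
#'   minimum detection floor.
#' @return the non-blank records with \code{value} background-subtracted,
#'   plus columns \code{below_detection} (logical) and \code{det_floor} (the
#'   per-record detection floor, same units as \code{value}). The estimated
#'   backgrounds are attached as attribute \code{"backgrounds"}.
#' @export
subtractBackground <- function(records, background = NULL, epsilon = 1e-3) {
  .requireColumns(records, .MEASUREMENT_COLS, "measurement table")
  isBlank <- records$strain_id == BLANK_SENTINEL
  grp <- paste(records$plate_id, records$replicate_id, records$channel,
               sep = "\r")
  blanks <- split(records$value[isBlank], grp[isBlank])
  groups <- unique(grp)
  bg <- floorAbove <- numeric(length(groups))
  names(bg) <- names(floorAbove) <- groups
  for (g in groups) {
    b <- blanks[[g]]
    if (is.null(b) || !length(b)) {
      ch <- sub("^.*\r", "", g)
      const <- if (is.null(background)) NA_real_
               else if (!is.null(names(background))) background[[ch]]
               else background[[1]]
      if (is.null(const) || is.na(const))
        .stopf("no blank wells for %s and no background constant supplied",
               gsub("\r", "/", g))
      bg[g] <- const
      floorAbove[g] <- epsilon
    } else {
      bg[g] <- stats::median(b)
      floorAbove[g] <- max(3 * stats::mad(b), epsilon)
    }
  }
  out <- records[!isBlank, , drop = FALSE]
  g <- grp[!isBlank]
  v <- out$value - bg[g]
  floorv <- floorAbove[g]
  below <- v < floorv
  v[below] <- floorv[below]
  out$value <- pmax(v, epsilon)
  out$below_detection <- below
  out$det_floor <- floorv
  rownames(out) <- NULL
  attr(out, "backgrounds") <-
    data.frame(do.call(rbind, strsplit(groups, "\r", fixed = TRUE)),
               background = unname(bg),
               detection_floor = unname(floorAbove)) |>
    stats::setNames(c("plate_id", "replicate_id", "channel", "background",
                      "detection_floor"))
  out
}

#' Correct luminescence by cell density
#'
#' Divides each well's background-subtracted luminescence by the matching
#' background-subtracted cell-density reading (fluorescence or OD600) from
#' the same (plate, replicate, well). Wells whose density is not positive
#' after its own background subtraction are excluded with a warning.
#'
#' @param records output of \code{\link{subtractBackground}} holding both the
#'   luminescence and the density channel; alternatively luminescence only,
#'   with the density records passed separately.
#' @param densityRecords optional data.frame of density-channel records.
#' @return luminescence records with \code{value} (and \code{det_floor})
#'   divided by the matched density; the \code{"backgrounds"} attribute is
#'   propagated.
#' @export
densityCorrect <- function(records, densityRecords = NULL) {
  if (is.null(densityRecords)) {
    isLum <- records$channel == "luminescence"
    densityRecords <- records[!isLum, , drop = FALSE]
    records <- records[isLum, , drop = FALSE]
  }
  if (!nrow(densityRecords))
    .stopf("no cell-density records to correct with")
  dch <- unique(densityRecords$channel)
  if (length(dch) != 1L)
    .stopf("density records must hold a single channel, got: %s",
           paste(dch, collapse = ", "))
  key <- function(df) paste(df$plate_id, df$replicate_id, df$well, sep = "\r")
  idx <- match(key(records), key(densityRecords))
  if (anyNA(idx))
    .stopf("no %s reading for well %s/%s/%s", dch,
           records$plate_id[which(is.na(idx))[1]],
           records$replicate_id[which(is.na(idx))[1]],
           records$well[which(is.na(idx))[1]])
  dens <- densityRecords$value[idx]
  # density at or below its own blank level carries no information
  invalid <- !is.finite(dens) | dens <= 0 |
    (if ("below_detection" %in% colnames(densityRecords))
       densityRecords$below_detection[idx] else FALSE)
  if (any(invalid))
    .warnf("excluding %d well(s) with invalid cell-density readings",
           sum(invalid))
  out <- records[!invalid, , drop = FALSE]
  out$value <- out$value / dens[!invalid]
  if ("det_floor" %in% colnames(out))
    out$det_floor <- out$det_floor / dens[!invalid]
  rownames(out) <- NULL
  attr(out, "backgrounds") <- attr(records, "backgrounds")
  out
}

#' Log2-transform corrected signals
#'
#' @param records output of \code{\link{densityCorrect}} (values positive by
#'   construction of the epsilon clamp).
#' @return records with \code{value} and \code{det_floor} log2-transformed;
#'   \code{below_detection} flags propagate unchanged.
#' @export
log2Transform <- function(records) {
  if (any(records$value <= 0))
    .stopf("log2 transform requires positive values; clamp upstream")
  out <- records
  out$value <- log2(out$value)
  if ("det_floor" %in% colnames(out)) out$det_floor <- log2(out$det_floor)
  attr(out, "backgrounds") <- attr(records, "backgrounds")
  out
}

#' Remove plate and day effects by regression against replicate medians
#'
#' For every plate read, the log2 signal of each strain is regressed (OLS by
#' default) against the median of that strain's signals across all
#' replicates. The fitted line \code{y = m x + b} captures the plate's
#' multiplicative/additive distortion; adjusted values invert it,
#' \code{(y - b) / m}, so all plate reads land on the cross-replicate median
#' scale. Plate reads with fewer than \code{minWells} finite values or a
#' fitted \code{|m|} below \code{slopeFloor} are left unadjusted and flagged;
#' a single-replicate input is returned unchanged with a warning.
#'
#' @param records log2 luminescence records (one row per strain and
#'   replicate).
#' @param minWells minimum finite values per plate read for a fit.
#' @param slopeFloor smallest |slope| considered invertible.
#' @param method \code{"invert"} (default, \code{(y - b)/m}) or
#'   \code{"residual"} (\code{y - (b + (m - 1) x)}).
#' @param fit \code{"ols"} or \code{"robust"} (Huber M-estimate via
#'   \code{MASS::rlm}).
#' @return records with adjusted \code{value} (and \code{det_floor}); the
#'   per-plate-read fits as attribute \code{"fits"} (columns plate_id,
#'   replicate_id, slope, intercept, n, adjusted).
#' @export
plateNormalize <- function(records, minWells = 10, slopeFloor = 0.1,
                           method = c("invert", "residual"),
                           fit = c("ols", "robust")) {
  method <- match.arg(method)
  fit <- match.arg(fit)
  reps <- unique(records$replicate_id)
  if (length(reps) < 2L) {
    .warnf("single replicate: plate normalization is the identity")
    attr(records, "fits") <- data.frame()
    return(records)
  }
  med <- tapply(records$value, records$strain_id, stats::median,
                na.rm = TRUE)
  x <- as.numeric(med[records$strain_id])
  grp <- paste(records$plate_id, records$replicate_id, sep = "\r")
  out <- records
  fits <- list()
  for (g in unique(grp)) {
    i <- which(grp == g)
    ok <- is.finite(x[i]) & is.finite(records$value[i])
    ids <- strsplit(g, "\r", fixed = TRUE)[[1]]
    if (sum(ok) < minWells) {
      fits[[g]] <- data.frame(plate_id = ids[1], replicate_id = ids[2],
                              slope = NA_real_, intercept = NA_real_,
                              n = sum(ok), adjusted = FALSE)
      next
    }
    xi <- x[i][ok]; yi <- records$value[i][ok]
    if (fit == "robust" && requireNamespace("MASS", quietly = TRUE)) {
      cf <- stats::coef(MASS::rlm(yi ~ xi, maxit = 50))
    } else {
      cf <- stats::coef(stats::lm.fit(cbind(1, xi), yi))
    }
    b <- cf[[1]]; m <- cf[[2]]
    adj <- is.finite(m) && abs(m) >= slopeFloor
    if (adj) {
      if (method == "invert") {
        out$value[i] <- (records$value[i] - b) / m
        if ("det_floor" %in% colnames(out))
          out$det_floor[i] <- (records$det_floor[i] - b) / m
      } else {
        out$value[i] <- records$value[i] - (b + (m - 1) * x[i])
        if ("det_floor" %in% colnames(out))
          out$det_floor[i] <- records$det_floor[i] - (b + (m - 1) * x[i])
      }
    }
    fits[[g]] <- data.frame(plate_id = ids[1], replicate_id = ids[2],
                            slope = m, intercept = b, n = sum(ok),
                            adjusted = adj)
  }
  attr(out, "backgrounds") <- attr(records, "backgrounds")
  attr(out, "fits") <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  out
}

#' Aggregate replicate signals into a PairSignalSet
#'
#' Builds the strains x replicates signal matrix, computes per-strain means
#' (strains with every replicate censored keep the mean of their detection
#' floors, flagged), drops strains with no valid replicate, and records
#' replicate-correlation QC plus the plate fits in the object metadata.
#'
#' @param records plate-normalized log2 records.
#' @param strainMap strain map data.frame; strains referenced by the records
#'   must be present.
#' @return a \code{\linkS4class{PairSignalSet}}.
#' @export
aggregateReplicates <- function(records, strainMap) {
  validateStrainMap(strainMap)
  orphan <- setdiff(unique(records$strain_id), strainMap$strain_id)
  if (length(orphan))
    .stopf("records reference unknown strain_id '%s'", orphan[1])
  reps <- sort(unique(records$replicate_id))
  strains <- unique(records$strain_id)
  mat <- matrix(NA_real_, length(strains), length(reps),
                dimnames = list(strains, reps))
  bd <- matrix(NA, length(strains), length(reps),
               dimnames = list(strains, reps))
  fl <- mat
  i <- cbind(match(records$strain_id, strains),
             match(records$replicate_id, reps))
  mat[i] <- records$value
  if ("below_detection" %in% colnames(records)) bd[i] <- records$below_detection
  if ("det_floor" %in% colnames(records)) fl[i] <- records$det_floor
  valid <- rowSums(is.finite(mat)) > 0
  if (any(!valid)) {
    .warnf("excluding %d strain(s) with no valid replicate", sum(!valid))
    mat <- mat[valid, , drop = FALSE]
    bd <- bd[valid, , drop = FALSE]
    fl <- fl[valid, , drop = FALSE]
    strains <- strains[valid]
  }
  mi <- match(strains, strainMap$strain_id)
  rd <- S4Vectors::DataFrame(
    bait = strainMap$bait[mi],
    prey = strainMap$prey[mi],
    mean_log2 = rowMeans(mat, na.rm = TRUE),
    below_detection_frac = rowMeans(bd, na.rm = TRUE),
    detection_limit_log2 = rowMeans(fl, na.rm = TRUE),
    row.names = strains)
  rd$below_detection_frac[is.nan(rd$below_detection_frac)] <- NA_real_
  qc <- if (ncol(mat) > 1)
    stats::cor(mat, use = "pairwise.complete.obs") else
    matrix(1, 1, 1, dimnames = list(reps, reps))
  se <- SummarizedExperiment(
    assays = list(log2signal = mat, belowDetection = bd),
    rowData = rd)
  metadata(se)$replicate_correlation <- qc
  metadata(se)$plate_fits <- attr(records, "fits")
  metadata(se)$backgrounds <- attr(records, "backgrounds")
  new("PairSignalSet", se)
}

#' Full normalization chain for one screen
#'
#' Convenience wrapper running background subtraction, density correction,
#' log2 transform, plate normalization and replicate aggregation.
#'
#' @param measurements long-format measurement data.frame (both channels).
#' @param strainMap strain map data.frame.
#' @param ... passed on to \code{\link{plateNormalize}}.
#' @inheritParams subtractBackground
#' @return a \code{\linkS4class{PairSignalSet}}.
#' @export
#' @examples
#' sim <- simulateScreen(exampleUniverse(), exampleNetwork(),
#'                       screenDesign(baits = "P01",
#'                                    preys = sprintf("P%02d", 2:12),
#'                                    replicates = 3, seed = 11))
#' normalizeScreen(sim@measurements, sim@strainMap)
normalizeScreen <- function(measurements, strainMap, background = NULL,
                            epsilon = 1e-3, ...) {
  sub <- subtractBackground(measurements, background = background,
                            epsilon = epsilon)
  corrected <- densityCorrect(sub)
  lg <- log2Transform(corrected)
  adj <- plateNormalize(lg, ...)
  aggregateReplicates(adj, strainMap)
}
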