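# Reading and writing plate measurement files, strain maps and result
# tables. Plate measurements travel in long (tidy) format:
#   plate_id,replicate_id,well,strain_id,channel,value
# Strain maps:
#   strain_id,bait,prey,tag_config,ploidy
# Result tables are written as TSV. All files UTF-8, "." decimal separator.

.MEASUREMENT_COLS <- c("plate_id", "replicate_id", "well", "strain_id",
                       "channel", "value")
.STRAINMAP_COLS <- c("strain_id", "bait", "prey", "tag_config", "ploidy")

#' Read a long-format plate measurement file
#'
#' Parses a CSV of per-well readings, one row per (plate, replicate, well,
#' channel). Wells are validated against the plate grid (row letters A-H or
#' A-P, 1-based zero-padded column numbers), values must be nonnegative and
#' finite, channels must be one of \code{luminescence}, \code{fluorescence},
#' \code{od600}, and the (plate, replicate, well, channel) key must be unique.
#' Medium-only wells carry the strain id \code{"BLANK"}.
#'
#' @param path path to a CSV file with header
#'   \code{plate_id,replicate_id,well,strain_id,channel,value}.
#' @param plateFormat 96 or 384; the grid wells are validated against.
#' @return data.frame with the six columns above, \code{value} numeric.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plate_id,replicate_id,well,strain_id,channel,value",
#'              "p1,r1,A01,s1,luminescence,1200",
#'              "p1,r1,A01,s1,fluorescence,340"), f)
#' readMeasurements(f)
readMeasurements <- function(path, plateFormat = 384) {
  if (!file.exists(path)) .stopf("measurement file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .requireColumns(df, .MEASUREMENT_COLS, "measurement file")
  df <- df[, .MEASUREMENT_COLS]
  df$value <- as.numeric(df$value)
  validateMeasurements(df, plateFormat = plateFormat)
  df
}

#' Validate an in-memory measurement table
#'
#' Applies the same contract as \code{\link{readMeasurements}} to a
#' data.frame. Called by the readers and by \code{\link{simulateScreen}}
#' consumers; errors name the offending row.
#'
#' @param records data.frame of measurement records.
#' @param plateFormat 96 or 384.
#' @return the records, invisibly, if valid.
#' @export
validateMeasurements <- function(records, plateFormat = 384) {
  .requireColumns(records, .MEASUREMENT_COLS, "measurement table")
  plateFormat <- as.integer(plateFormat)
  bad <- .badWells(records$well, plateFormat)
  if (length(bad))
    .stopf("malformed well '%s' for a %d-well plate (row %d)",
           records$well[bad[1]], plateFormat, bad[1])
  badv <- which(!is.finite(records$value) | records$value < 0)
  if (length(badv))
    .stopf("negative or non-finite value at row %d", badv[1])
  badc <- which(!records$channel %in% .CHANNELS)
  if (length(badc))
    .stopf("unknown channel '%s' at row %d (expected %s)",
           records$channel[badc[1]], badc[1],
           paste(.CHANNELS, collapse = "/"))
  key <- paste(records$plate_id, records$replicate_id, records$well,
               records$channel, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    .stopf("duplicate (plate, replicate, well, channel) key at row %d: %s/%s/%s/%s",
           dup[1], records$plate_id[dup[1]], records$replicate_id[dup[1]],
           records$well[dup[1]], records$channel[dup[1]])
  invisible(records)
}

#' Write a long-format plate measurement file
#'
#' Inverse of \code{\link{readMeasurements}}: a round trip through disk
#' reproduces the records exactly (up to numeric formatting at full
#' precision).
#'
#' @param records data.frame of measurement records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMeasurements <- function(records, path) {
  .requireColumns(records, .MEASUREMENT_COLS, "measurement table")
  utils::write.csv(format_numeric(records[, .MEASUREMENT_COLS]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision numeric formatting so CSV round trips are lossless.
format_numeric <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df
}

#' Read a strain map
#'
#' A strain map links each arrayed strain to its bait and prey proteins, the
#' reporter configuration (\code{NanoBiT} split-reporter pairs or
#' \code{NanoLuc} full-length abundance reporters, for which the prey field
#' repeats the bait), and the strain ploidy (diploid for homomeric pairs,
#' haploid otherwise).
#'
#' @param path CSV with header \code{strain_id,bait,prey,tag_config,ploidy}.
#' @return data.frame with those five columns.
#' @export
readStrainMap <- function(path) {
  if (!file.exists(path)) .stopf("strain map not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .requireColumns(df, .STRAINMAP_COLS, "strain map")
  df <- df[, .STRAINMAP_COLS]
  if (nrow(df) == 0L) {
    .warnf("strain map '%s' is empty", path)
    return(df)
  }
  validateStrainMap(df)
  df
}

#' Validate an in-memory strain map
#' @param map data.frame of strain map rows.
#' @return the map, invisibly, if valid.
#' @export
validateStrainMap <- function(map) {
  .requireColumns(map, .STRAINMAP_COLS, "strain map")
  dup <- which(duplicated(map$strain_id))
  if (length(dup))
    .stopf("duplicate strain_id '%s' at row %d", map$strain_id[dup[1]], dup[1])
  badt <- which(!map$tag_config %in% c("NanoBiT", "NanoLuc"))
  if (length(badt))
    .stopf("unknown tag_config '%s' at row %d", map$tag_config[badt[1]],
           badt[1])
  badp <- which(!map$ploidy %in% c("haploid", "diploid"))
  if (length(badp))
    .stopf("unknown ploidy '%s' at row %d", map$ploidy[badp[1]], badp[1])
  luc <- map$tag_config == "NanoLuc" & map$bait != map$prey
  if (any(luc))
    .stopf("NanoLuc strain '%s' must repeat the bait in the prey field",
           map$strain_id[which(luc)[1]])
  invisible(map)
}

#' Write a strain map
#' @param map data.frame of strain map rows.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeStrainMap <- function(map, path) {
  .requireColumns(map, .STRAINMAP_COLS, "strain map")
  utils::write.csv(map[, .STRAINMAP_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Join measurements to a strain map
#'
#' Attaches bait/prey/tag/ploidy columns to measurement records by
#' \code{strain_id}. Blank wells pass through with NA annotation; any other
#' strain id absent from the map is an error naming the orphan.
#'
#' @param records measurement data.frame.
#' @param map strain map data.frame.
#' @return the records with \code{bait}, \code{prey}, \code{tag_config},
#'   \code{ploidy} columns appended.
#' @export
joinStrainMap <- function(records, map) {
  validateStrainMap(map)
  idx <- match(records$strain_id, map$strain_id)
  orphan <- is.na(idx) & records$strain_id != BLANK_SENTINEL
  if (any(orphan))
    .stopf("measurement references unknown strain_id '%s' (not in strain map)",
           records$strain_id[which(orphan)[1]])
  cbind(records,
        map[idx, c("bait", "prey", "tag_config", "ploidy"), drop = FALSE],
        row.names = NULL)
}

#' Convert a plate-matrix export to long format
#'
#' Plate readers commonly export one value matrix per plate (rows A.. as
#' matrix rows, columns 1.. as matrix columns). This converts such a matrix
#' to the long record format for one channel.
#'
#' @param mat numeric matrix, 8 x 12 or 16 x 24; dimnames optional (defaults
#'   to the standard grid).
#' @param plateId,replicateId identifiers for the emitted records.
#' @param channel one of \code{luminescence}, \code{fluorescence},
#'   \code{od600}.
#' @param strainWells optional named character vector well -> strain_id;
#'   wells absent from it are emitted as \code{"BLANK"}.
#' @return long-format measurement data.frame.
#' @export
plateMatrixToLong <- function(mat, plateId, replicateId,
                              channel = "luminescence", strainWells = NULL) {
  if (!is.matrix(mat) ||
      !((nrow(mat) == 8 && ncol(mat) == 12) ||
        (nrow(mat) == 16 && ncol(mat) == 24)))
    .stopf("plate matrix must be 8x12 or 16x24, got %dx%d",
           nrow(mat), ncol(mat))
  format <- if (nrow(mat) == 8) 96L else 384L
  wells <- .wellIds(format)
  values <- as.vector(t(mat))
  strain <- rep(BLANK_SENTINEL, length(wells))
  if (!is.null(strainWells)) {
    hit <- match(wells, names(strainWells))
    strain[!is.na(hit)] <- strainWells[hit[!is.na(hit)]]
  }
  keep <- !is.na(values)
  data.frame(plate_id = plateId, replicate_id = replicateId,
             well = wells[keep], strain_id = strain[keep],
             channel = channel, value = values[keep],
             stringsAsFactors = FALSE)
}

#' Write a result table as TSV
#'
#' Generic TSV writer used for ratio results, metric curves and differential
#' matrices; UTF-8, "." decimal separator, no quoting.
#'
#' @param records data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
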