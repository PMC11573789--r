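# Internal helpers shared across modules: well-grid arithmetic, unordered
# pair keys, and small input checks.

.plateRows <- function(format) {
  if (format == 96L) LETTERS[1:8] else LETTERS[1:16]
}

.plateCols <- function(format) {
  if (format == 96L) 12L else 24L
}

# All well ids of a plate format, row-major, zero-padded ("A01".."P24").
.wellIds <- function(format) {
  rows <- .plateRows(format)
  cols <- seq_len(.plateCols(format))
  as.vector(t(outer(rows, cols, function(r, cc) sprintf("%s%02d", r, cc))))
}

# Validate well strings against a plate format; returns indices of bad wells.
.badWells <- function(wells, format) {
  ok <- grepl("^[A-P][0-9]{2}$", wells)
  row <- substr(wells, 1, 1)
  col <- suppressWarnings(as.integer(substr(wells, 2, 3)))
  ok <- ok & row %in% .plateRows(format) &
    !is.na(col) & col >= 1L & col <= .plateCols(format)
  which(!ok)
}

#' Canonical unordered key for a protein pair
#'
#' Interaction pairs are unordered: \code{pairKey("A", "B")} and
#' \code{pairKey("B", "A")} are identical. Homodimers are allowed. Vectorized.
#'
#' @param a,b character vectors of protein ids (recycled to equal length).
#' @return character vector of keys of the form \code{"A|B"} with the two ids
#'   sorted.
#' @export
#' @examples
#' pairKey(c("UPF1", "NMD2"), c("NMD2", "UPF1"))
pairKey <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Named-column presence check for data.frame inputs read from disk.
.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    .stopf("%s is missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  invisible(df)
}
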