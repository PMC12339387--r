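#' Build a genome description
#'
#' A genome is an ordered table of chromosome names and lengths; it anchors
#' coordinate validation for every interval, loop and contact map in the
#' package. Coordinates throughout are 0-based half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A tibble with class `ld_genome` and columns `chrom`, `length`.
#' @examples
#' genome_def(c("chr1", "chr2"), c(5e7, 3e7))
#' @export
genome_def <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  structure(tibble::tibble(chrom = chrom, length = length),
            class = c("ld_genome", class(tibble::tibble())))
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TAB-separated `chrom<TAB>length` file.
#' @return An `ld_genome` tibble.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_def(df$chrom, df$length)
}

#' Write a chrom.sizes file
#'
#' @param genome An `ld_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(as.data.frame(genome[, c("chrom", "length")]), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

n_bins <- function(genome, chrom, resolution) {
  as.integer(ceiling(chrom_length(genome, chrom) / resolution))
}

#' Validate a table of genomic intervals
#'
#' Checks the half-open interval invariants `0 <= start < end` and, when a
#' genome is supplied, that chromosomes are known and `end` does not exceed
#' the chromosome length.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param genome Optional `ld_genome` to validate against.
#' @return The input as a tibble, invisibly usable in pipes.
#' @export
validate_intervals <- function(intervals, genome = NULL) {
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  }
  if (!is.null(genome)) {
    len <- chrom_length(genome, intervals$chrom)
    over <- which(intervals$end > len)
    if (length(over)) stop("interval exceeds chromosome length at row ", over[1])
  }
  intervals
}

# Half-open overlap via IRanges; returns logical vector over `query` rows:
# does the query interval overlap >=1 subject interval (>=1 shared bp)?
overlaps_any_intervals <- function(query, subject) {
  out <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(out)
  for (cn in unique(query$chrom)) {
    qi <- which(query$chrom == cn)
    si <- which(subject$chrom == cn)
    if (!length(si)) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    out[qi] <- IRanges::overlapsAny(qr, sr)
  }
  out
}
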