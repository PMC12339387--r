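#' Construct a binned cis contact map
#'
#' A contact map stores, per chromosome, the upper triangle of a binned
#' cis contact matrix as a sparse pixel table. Pixels are keyed by 0-based
#' bin indices with `bin1 <= bin2`; input pixels with `bin1 > bin2` are
#' transposed and duplicate keys are summed, so the stored map is symmetric
#' by construction.
#'
#' @param pixels Data frame with columns `chrom`, `bin1`, `bin2`, `count`
#'   (non-negative, finite).
#' @param genome An `ld_genome`.
#' @param resolution Bin size in bp.
#' @param balanced Logical; whether `count` holds balanced values.
#' @param bias Optional named list (per chromosome) of per-bin bias vectors
#'   (NA where the bin is masked).
#' @param mask Optional named list (per chromosome) of logical usable-bin
#'   indicators. Defaults to all bins usable.
#' @return A `contact_map` object.
#' @export
contact_map <- function(pixels, genome, resolution, balanced = FALSE,
                        bias = NULL, mask = NULL) {
  pixels <- tibble::as_tibble(pixels)
  stopifnot(all(c("chrom", "bin1", "bin2", "count") %in% names(pixels)))
  if (any(!is.finite(pixels$count)) || any(pixels$count < 0)) {
    stop("pixel values must be finite and >= 0")
  }
  nb <- n_bins(genome, pixels$chrom, resolution)
  if (any(pixels$bin1 < 0) || any(pixels$bin1 >= nb) || any(pixels$bin2 >= nb)) {
    stop("bin index outside chromosome")
  }
  swap <- pixels$bin1 > pixels$bin2
  if (any(swap)) {
    tmp <- pixels$bin1[swap]
    pixels$bin1[swap] <- pixels$bin2[swap]
    pixels$bin2[swap] <- tmp
  }
  pixels <- aggregate_pixels(pixels)
  if (is.null(mask)) {
    mask <- lapply(stats::setNames(genome$chrom, genome$chrom), function(cn) {
      rep(TRUE, n_bins(genome, cn, resolution))
    })
  }
  structure(list(pixels = pixels, genome = genome,
                 resolution = as.integer(resolution),
                 balanced = isTRUE(balanced), bias = bias, mask = mask),
            class = "contact_map")
}

# Sort pixels by (chrom, bin1, bin2) and sum duplicate keys. Pure vector
# arithmetic on a composite numeric key; exact below 2^53, i.e. for any
# realistic bin count.
aggregate_pixels <- function(pixels) {
  n <- nrow(pixels)
  if (n == 0L) {
    pixels$bin1 <- as.integer(pixels$bin1)
    pixels$bin2 <- as.integer(pixels$bin2)
    return(pixels)
  }
  c_id <- as.integer(factor(pixels$chrom))
  B <- max(pixels$bin2) + 1
  key <- (as.numeric(c_id) * B + pixels$bin1) * B + pixels$bin2
  ord <- order(key)
  k <- key[ord]
  first <- c(TRUE, k[-1] != k[-n])
  out <- tibble::tibble(chrom = pixels$chrom[ord][first],
                        bin1 = as.integer(pixels$bin1[ord][first]),
                        bin2 = as.integer(pixels$bin2[ord][first]))
  if (all(first)) {
    out$count <- pixels$count[ord]
  } else {
    cs <- cumsum(pixels$count[ord])
    ends <- c(which(first)[-1] - 1L, n)
    out$count <- cs[ends] - c(0, cs[ends[-length(ends)]])
  }
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d px | %d chrom | res %d bp | %s\n",
              nrow(x$pixels), nrow(x$genome), x$resolution,
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' @export
tidy.contact_map <- function(x, ...) x$pixels

map_chroms <- function(map) unique(map$pixels$chrom)

chrom_pixels <- function(map, chrom) {
  map$pixels[map$pixels$chrom == chrom, , drop = FALSE]
}

chrom_mask <- function(map, chrom) {
  m <- map$mask[[chrom]]
  if (is.null(m)) rep(TRUE, n_bins(map$genome, chrom, map$resolution)) else m
}

chrom_bias <- function(map, chrom) {
  b <- map$bias[[chrom]]
  if (is.null(b)) rep(1, n_bins(map$genome, chrom, map$resolution)) else b
}

# Band representation of one chromosome: matrix M[i, d+1] = value at pixel
# (i-1, i-1+d), rows over bins, columns over bin distances 0..dmax.
band_matrix <- function(map, chrom, dmax) {
  n <- n_bins(map$genome, chrom, map$resolution)
  px <- chrom_pixels(map, chrom)
  d <- px$bin2 - px$bin1
  keep <- d <= dmax
  M <- matrix(0, nrow = n, ncol = dmax + 1L)
  M[cbind(px$bin1[keep] + 1L, d[keep] + 1L)] <- px$count[keep]
  M
}

# Validity band: TRUE where both bins exist, are mappable, and d within range.
band_valid <- function(map, chrom, dmax) {
  n <- n_bins(map$genome, chrom, map$resolution)
  m <- chrom_mask(map, chrom)
  V <- matrix(FALSE, nrow = n, ncol = dmax + 1L)
  for (d in 0:dmax) {
    if (d >= n) break
    idx <- 1:(n - d)
    V[idx, d + 1L] <- m[idx] & m[idx + d]
  }
  V
}

#' Aggregate a contact map to a coarser resolution
#'
#' Sums raw pixel counts into bins of `factor` times the current bin size;
#' used e.g. to derive 100-kb compartment maps from 10-kb loop-calling maps.
#' Only raw (unbalanced) maps can be coarsened.
#'
#' @param map A raw `contact_map`.
#' @param factor Integer >= 1; new resolution = `factor * resolution`.
#' @return A raw `contact_map` at the coarser resolution.
#' @export
coarsen_map <- function(map, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (map$balanced) stop("coarsen the raw map, then re-balance")
  px <- map$pixels
  px$bin1 <- px$bin1 %/% factor
  px$bin2 <- px$bin2 %/% factor
  contact_map(px, map$genome, map$resolution * factor, balanced = FALSE)
}

#' Write a contact map in the portable COO text dialect
#'
#' Format: header lines `#resolution=<int>` and `#balanced=<true|false>`,
#' then TAB-separated `chrom start1 start2 value` rows where starts are bin
#' start coordinates in bp.
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#resolution=%d", map$resolution),
               sprintf("#balanced=%s", if (map$balanced) "true" else "false")),
             con)
  px <- map$pixels
  if (nrow(px)) {
    utils::write.table(
      data.frame(px$chrom, px$bin1 * as.numeric(map$resolution),
                 px$bin2 * as.numeric(map$resolution),
                 format(px$count, digits = 15, scientific = FALSE, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a contact map from the COO text dialect
#'
#' @param path Input path (see [write_contact_map()] for the format).
#' @param genome An `ld_genome`; every chromosome in the file must be known.
#' @param resolution Expected bin size in bp; must match the file header
#'   when one is present.
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path, genome, resolution) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  res_hdr <- sub("^#resolution=", "", grep("^#resolution=", hdr, value = TRUE))
  if (length(res_hdr) && as.integer(res_hdr[1]) != resolution) {
    stop("file resolution ", res_hdr[1], " does not match requested ", resolution)
  }
  bal_hdr <- sub("^#balanced=", "", grep("^#balanced=", hdr, value = TRUE))
  balanced <- length(bal_hdr) > 0 && identical(tolower(bal_hdr[1]), "true")
  if (!length(body)) {
    return(contact_map(tibble::tibble(chrom = character(), bin1 = integer(),
                                      bin2 = integer(), count = numeric()),
                       genome, resolution, balanced = balanced))
  }
  f <- utils::read.table(text = body, sep = "\t",
                         col.names = c("chrom", "start1", "start2", "count"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (any(f$start1 %% resolution != 0) || any(f$start2 %% resolution != 0)) {
    stop("pixel coordinate is not a multiple of the resolution")
  }
  if (!all(f$chrom %in% genome$chrom)) {
    stop("unknown chromosome in contact map: ",
         paste(setdiff(unique(f$chrom), genome$chrom), collapse = ", "))
  }
  contact_map(tibble::tibble(chrom = f$chrom,
                             bin1 = f$start1 %/% resolution,
                             bin2 = f$start2 %/% resolution,
                             count = f$count),
              genome, resolution, balanced = balanced)
}
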