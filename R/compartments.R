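#' A/B compartment eigenvector track
#'
#' Classic construction: per chromosome the observed/expected matrix over
#' mappable bins (clipped to `clip` to tame sparse outliers), its Pearson
#' correlation matrix across bin profiles, and the eigenvector of the
#' largest-magnitude eigenvalue, scaled by `sqrt(|eigenvalue|)`. The global
#' sign is fixed by requiring non-negative correlation with the phasing
#' track (GC-content-like, e.g. +1/-1 per compartment block).
#'
#' @param map A balanced `contact_map` at compartment resolution
#'   (typically 100 kb).
#' @param expected Its expected profile.
#' @param phasing Interval tibble (`chrom`, `start`, `end`, `value`)
#'   covering the mappable bins, e.g. from [read_intervals()] on a
#'   bedGraph.
#' @param sample_id Optional sample label.
#' @param clip O/E clipping range before correlation
#'   (default `c(0.01, 100)`).
#' @param min_bins Chromosomes with fewer mappable bins are skipped with a
#'   warning (default 10).
#' @return An `eigen_track` tibble (`chrom`, `bin`, `start`, `end`, `e1`;
#'   NA on masked/undefined bins) with attributes `sample_id`, `resolution`
#'   and `degenerate`.
#' @export
compartment_eigenvector <- function(map, expected, phasing,
                                    sample_id = NULL,
                                    clip = c(0.01, 100), min_bins = 10L) {
  if (!map$balanced) stop("compartment eigenvector requires a balanced map")
  res <- map$resolution
  degenerate <- FALSE
  out <- list()
  for (cn in map_chroms(map)) {
    n <- n_bins(map$genome, cn, res)
    e1 <- rep(NA_real_, n)
    m <- chrom_mask(map, cn)
    if (sum(m) < min_bins) {
      warning("skipping ", cn, ": fewer than ", min_bins, " mappable bins")
    } else {
      px <- chrom_pixels(map, cn)
      e <- expected_vector(expected, cn, n - 1L)
      O <- matrix(0, n, n)
      oe <- px$count / e[px$bin2 - px$bin1 + 1L]
      O[cbind(px$bin1 + 1L, px$bin2 + 1L)] <- oe
      O[cbind(px$bin2 + 1L, px$bin1 + 1L)] <- oe
      idx <- which(m)
      O <- O[idx, idx, drop = FALSE]
      O[!is.finite(O)] <- 0
      O <- pmin(pmax(O, clip[1]), clip[2])
      sds <- apply(O, 2, stats::sd)
      if (all(sds == 0)) {
        degenerate <- TRUE
        e1[idx] <- 0
      } else {
        ok <- sds > 0
        C <- suppressWarnings(stats::cor(O[, ok, drop = FALSE]))
        C[!is.finite(C)] <- 0
        ev <- eigen(C, symmetric = TRUE)
        lead <- which.max(abs(ev$values))
        v <- ev$vectors[, lead] * sqrt(abs(ev$values[lead]))
        e1[idx[ok]] <- v
        ph <- phasing_bins(phasing, cn, res, n)
        def <- !is.na(e1) & !is.na(ph)
        if (sum(def) >= 3L) {
          r <- suppressWarnings(stats::cor(e1[def], ph[def]))
          if (is.finite(r) && r < 0) e1 <- -e1
        }
      }
    }
    out[[cn]] <- tibble::tibble(chrom = cn, bin = 0:(n - 1L),
                                start = (0:(n - 1L)) * res,
                                end = pmin((1:n) * res,
                                           chrom_length(map$genome, cn)),
                                e1 = e1)
  }
  track <- dplyr::bind_rows(out)
  attr(track, "sample_id") <- sample_id
  attr(track, "resolution") <- res
  attr(track, "degenerate") <- degenerate
  class(track) <- c("eigen_track", class(track))
  track
}

phasing_bins <- function(phasing, chrom, resolution, n) {
  ph <- rep(NA_real_, n)
  sub <- phasing[phasing$chrom == chrom, , drop = FALSE]
  if (!nrow(sub) || !"value" %in% names(sub)) return(ph)
  first_bin <- as.integer(sub$start %/% resolution)
  last_bin <- as.integer((sub$end - 1) %/% resolution)
  for (k in seq_len(nrow(sub))) {
    b <- first_bin[k]:min(last_bin[k], n - 1L)
    ph[b + 1L] <- sub$value[k]
  }
  ph
}

#' Pairwise sample correlation of eigenvector tracks on variable bins
#'
#' Keeps bins whose eigenvector value is defined and nonzero in every
#' track, ranks them by across-sample variance, keeps the top `top_frac`,
#' and computes pairwise Pearson correlations restricted to those bins.
#'
#' @param tracks Named list of `eigen_track`s (same genome/resolution).
#' @param top_frac Fraction of most-variable bins to keep (default 0.25).
#' @return A symmetric correlation matrix with unit diagonal, sample ids
#'   as dimnames.
#' @export
variable_bin_correlation <- function(tracks, top_frac = 0.25) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  if (is.null(names(tracks))) {
    names(tracks) <- vapply(seq_along(tracks), function(k) {
      id <- attr(tracks[[k]], "sample_id")
      if (is.null(id)) sprintf("S%d", k) else id
    }, "")
  }
  E <- vapply(tracks, function(tr) tr$e1, numeric(nrow(tracks[[1]])))
  common <- rowSums(is.na(E) | E == 0) == 0L
  if (!any(common)) stop("no bins defined and nonzero in all tracks")
  E <- E[common, , drop = FALSE]
  v <- apply(E, 1, stats::var)
  keep <- v >= stats::quantile(v, 1 - top_frac)
  stats::cor(E[keep, , drop = FALSE])
}

#' Hierarchically cluster samples from a correlation matrix
#'
#' Average-linkage (by default) hierarchical clustering on the distance
#' `1 - r`. Samples are ordered lexicographically by id before clustering
#' so tie-breaking is deterministic.
#'
#' @param corr Square symmetric correlation matrix with unit diagonal.
#' @param linkage hclust method (default "average").
#' @param k Number of flat clusters to cut (default 2).
#' @return A list with `hclust` (the dendrogram) and `labels` (named
#'   integer cluster assignment).
#' @export
cluster_samples <- function(corr, linkage = "average", k = 2L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("corr must be symmetric with unit diagonal")
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - corr), method = linkage)
  labels <- stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels)
}
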