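#' ICE matrix balancing
#'
#' Iterative correction of a raw cis contact map: per chromosome, bin biases
#' are updated by `b_i <- b_i * m_i / mean(m)` where `m_i` is the current
#' corrected marginal of bin `i` over mappable bins, until the maximum
#' relative marginal deviation falls below `tol` or `max_iter` is reached.
#' Bins with zero raw marginal are masked (bias undefined, NA) and excluded
#' from every downstream statistic. On return biases are rescaled so the
#' mean bias over mappable bins is 1.
#'
#' @param map A raw `contact_map`.
#' @param max_iter Maximum number of iterations (default 200).
#' @param tol Convergence tolerance on the maximum relative marginal
#'   deviation (default 1e-5).
#' @return A balanced `contact_map` carrying the per-bin `bias` list and
#'   updated usable-bin `mask`.
#' @export
ice_balance <- function(map, max_iter = 200L, tol = 1e-5) {
  if (map$balanced) stop("map is already balanced")
  stopifnot(tol > 0)
  if (nrow(map$pixels) == 0L) stop("cannot balance an empty map")
  pieces <- list(); bias <- list(); mask <- list()
  for (cn in map$genome$chrom) {
    n <- n_bins(map$genome, cn, map$resolution)
    px <- chrom_pixels(map, cn)
    if (nrow(px) == 0L) {
      bias[[cn]] <- rep(NA_real_, n)
      mask[[cn]] <- rep(FALSE, n)
      next
    }
    A <- Matrix::sparseMatrix(i = px$bin1 + 1L, j = px$bin2 + 1L,
                              x = px$count, dims = c(n, n), symmetric = TRUE)
    raw_marg <- as.numeric(A %*% rep(1, n))
    mappable <- raw_marg > 0
    if (!any(mappable)) stop("all bins empty on ", cn)
    b <- rep(1, n)
    for (it in seq_len(max_iter)) {
      m <- as.numeric(A %*% (1 / b)) / b
      s <- m[mappable]
      dev <- max(abs(s / mean(s) - 1))
      b[mappable] <- b[mappable] * s / mean(s)
      if (dev < tol) break
    }
    b <- b / mean(b[mappable])
    b[!mappable] <- NA_real_
    bias[[cn]] <- b
    mask[[cn]] <- mappable
    px$count <- px$count / (b[px$bin1 + 1L] * b[px$bin2 + 1L])
    px <- px[is.finite(px$count), , drop = FALSE]
    pieces[[cn]] <- px
  }
  contact_map(dplyr::bind_rows(pieces), map$genome, map$resolution,
              balanced = TRUE, bias = bias, mask = mask)
}

#' Expected contact value by bin distance
#'
#' For each chromosome of a balanced map, `e[d]` is the mean balanced value
#' over all mappable-bin pairs at bin distance `d`, counting absent pixels
#' as zero (sum over pixels / number of mappable pairs, not / nnz) — this
#' keeps observed/expected unbiased on sparse maps.
#'
#' @param map A balanced `contact_map`.
#' @param max_dist_bins Optional cap on the bin distance (default: full
#'   chromosome).
#' @return An `expected_profile` tibble with columns `chrom`, `dist`
#'   (bins), `expected`, `n_pairs`, and the resolution as an attribute.
#' @export
compute_expected <- function(map, max_dist_bins = NULL) {
  if (!map$balanced) stop("expected profile requires a balanced map")
  out <- list()
  for (cn in map_chroms(map)) {
    n <- n_bins(map$genome, cn, map$resolution)
    m <- as.numeric(chrom_mask(map, cn))
    dmax <- if (is.null(max_dist_bins)) n - 1L else min(max_dist_bins, n - 1L)
    px <- chrom_pixels(map, cn)
    d <- px$bin2 - px$bin1
    keep <- d <= dmax
    sums <- numeric(dmax + 1L)
    if (any(keep)) {
      agg <- rowsum(px$count[keep], d[keep])
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    npairs <- if (all(m == 1)) {
      n - (0:dmax)
    } else {
      vapply(0:dmax, function(dd) {
        sum(m[seq_len(n - dd)] * m[seq_len(n - dd) + dd])
      }, 0)
    }
    out[[cn]] <- tibble::tibble(chrom = cn, dist = 0:dmax,
                                expected = ifelse(npairs > 0, sums / npairs,
                                                  NA_real_),
                                n_pairs = npairs)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "resolution") <- map$resolution
  class(res) <- c("expected_profile", class(res))
  res
}

expected_vector <- function(expected, chrom, dmax) {
  e <- rep(NA_real_, dmax + 1L)
  sub <- expected[expected$chrom == chrom & expected$dist <= dmax, ]
  e[sub$dist + 1L] <- sub$expected
  e
}

#' Marginal coefficient of variation of a balanced map
#'
#' Diagnostic for balancing quality: per chromosome, the coefficient of
#' variation (sd/mean) of the balanced marginals over mappable bins.
#'
#' @param map A balanced `contact_map`.
#' @return A tibble with `chrom` and `marginal_cv`.
#' @export
marginal_cv <- function(map) {
  out <- purrr::map(map_chroms(map), function(cn) {
    n <- n_bins(map$genome, cn, map$resolution)
    px <- chrom_pixels(map, cn)
    A <- Matrix::sparseMatrix(i = px$bin1 + 1L, j = px$bin2 + 1L,
                              x = px$count, dims = c(n, n), symmetric = TRUE)
    marg <- as.numeric(A %*% rep(1, n))[chrom_mask(map, cn)]
    tibble::tibble(chrom = cn,
                   marginal_cv = stats::sd(marg) / mean(marg))
  })
  dplyr::bind_rows(out)
}
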