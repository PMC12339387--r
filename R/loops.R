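# Local-background loop statistics on the band representation.
#
# The caller is a HiCCUPS-style multi-neighborhood Poisson test: for each
# pixel, the local background is the distance-expected value scaled by the
# largest mean O/E over the local neighborhoods (donut ring, lower-left
# quadrant, and the four one-sided horizontal/vertical stripes between
# bg_inner and bg_outer), and the raw-equivalent observed count is tested
# against the raw-rescaled local background with an upper-tail Poisson
# probability.

# Shift a band matrix: result[i, d] = M[i + di, d + dd], zero outside.
shift_band <- function(M, di, dd) {
  n <- nrow(M); D <- ncol(M)
  R <- matrix(0, n, D)
  r1 <- max(1L, 1L - di); r2 <- min(n, n - di)
  c1 <- max(1L, 1L - dd); c2 <- min(D, D - dd)
  if (r1 > r2 || c1 > c2) return(R)
  R[r1:r2, c1:c2] <- M[(r1 + di):(r2 + di), (c1 + dd):(c2 + dd)]
  R
}

# The stripe neighborhoods are split into their two sides so that, when the
# pixel sits near a compartment-block boundary, at least one stripe stays
# within the pixel's own O/E regime; the max over neighborhoods then tracks
# the correct local background instead of a cross-compartment mixture.
neighborhood_offsets <- function(bg_inner, bg_outer) {
  g <- expand.grid(di = -bg_outer:bg_outer, dj = -bg_outer:bg_outer)
  cheb <- pmax(abs(g$di), abs(g$dj))
  ring <- cheb > bg_inner & cheb <= bg_outer
  list(
    donut = g[ring & g$di != 0 & g$dj != 0, ],
    lower_left = g[g$di >= 1 & g$dj <= -1 &
                     !(g$di <= bg_inner & g$dj >= -bg_inner), ],
    horizontal_left = g[g$di == 0 & g$dj < -bg_inner & g$dj >= -bg_outer, ],
    horizontal_right = g[g$di == 0 & g$dj > bg_inner & g$dj <= bg_outer, ],
    vertical_up = g[g$dj == 0 & g$di < -bg_inner & g$di >= -bg_outer, ],
    vertical_down = g[g$dj == 0 & g$di > bg_inner & g$di <= bg_outer, ],
    box = g)
}

# Sum of shifted copies of M over a set of (di, dj) pixel offsets.
# In band coordinates a pixel offset (di, dj) is a shift (di, dj - di).
offset_sum <- function(M, offsets) {
  R <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(nrow(offsets))) {
    R <- R + shift_band(M, offsets$di[k], offsets$dj[k] - offsets$di[k])
  }
  R
}

# Per-chromosome stat surface used by call_loops, pixel_stats and the
# pairwise differential test.
loop_stat_surface <- function(map, expected, chrom, max_dist_bins,
                              bg_outer = 5L, bg_inner = 2L,
                              pseudo_scale = 1) {
  n <- n_bins(map$genome, chrom, map$resolution)
  dmax_test <- min(max_dist_bins, n - 1L)
  dmax <- min(dmax_test + 2L * bg_outer, n - 1L)
  B <- band_matrix(map, chrom, dmax)
  V <- band_valid(map, chrom, dmax)
  e <- expected_vector(expected, chrom, dmax)
  e[!is.finite(e)] <- NA_real_
  OE <- sweep(B, 2, e, "/")
  OE[!V | !is.finite(OE)] <- 0
  Vnum <- V * 1

  bias <- chrom_bias(map, chrom)
  has_bias <- !is.null(map$bias[[chrom]])
  bb <- matrix(NA_real_, n, dmax + 1L)
  for (d in 0:dmax) {
    idx <- seq_len(n - d)
    bb[idx, d + 1L] <- bias[idx] * bias[idx + d]
  }
  if (!has_bias) bb[] <- 1 / pseudo_scale

  offs <- neighborhood_offsets(bg_inner, bg_outer)
  OEv <- OE * Vnum
  # 1 / raw-expected per cell: weights the information each neighborhood
  # cell contributes to the O/E mean (raw counts are what fluctuate).
  IE <- 1 / (sweep(matrix(1, n, dmax + 1L), 2, e, "*") * bb)
  IE[!V | !is.finite(IE)] <- 0
  bg_oe <- NULL; bg_n <- NULL; bg_h <- NULL
  for (nb in setdiff(names(offs), "box")) {
    ssum <- offset_sum(OEv, offs[[nb]])
    scnt <- offset_sum(Vnum, offs[[nb]])
    hsum <- offset_sum(IE, offs[[nb]])
    m <- ifelse(scnt > 0, ssum / scnt, NA_real_)
    if (is.null(bg_oe)) {
      bg_oe <- m; bg_n <- scnt; bg_h <- hsum
    } else {
      upd <- !is.na(m) & (is.na(bg_oe) | m > bg_oe)
      bg_oe[upd] <- m[upd]; bg_n[upd] <- scnt[upd]; bg_h[upd] <- hsum[upd]
    }
  }
  # Effective gamma shape of the background estimate: CV^2(lambda_hat) =
  # sum(1/raw_exp) / (OE_bg * N^2), so shape = OE_bg * N^2 / H.
  bg_size <- ifelse(!is.na(bg_oe) & bg_oe > 0 & bg_h > 0,
                    bg_oe * bg_n^2 / bg_h, Inf)
  nz_cnt <- offset_sum((B > 0) * Vnum, offs$box)
  tot_cnt <- offset_sum(Vnum, offs$box)
  zero_frac <- ifelse(tot_cnt > 0, 1 - nz_cnt / tot_cnt, 1)

  raw_obs <- B * bb
  lambda_bal <- sweep(bg_oe, 2, e, "*")
  lambda_raw <- lambda_bal * bb

  list(chrom = chrom, n = n, dmax = dmax, dmax_test = dmax_test,
       B = B, V = V, e = e, OE = OE, bg_oe = bg_oe, bg_size = bg_size,
       lambda_bal = lambda_bal, lambda_raw = lambda_raw,
       raw_obs = raw_obs, zero_frac = zero_frac)
}

surface_for_map <- function(map, expected, max_dist, bg_outer = 5L,
                            bg_inner = 2L, pseudo_scale = 1) {
  if (!map$balanced) stop("loop statistics require a balanced map")
  max_dist_bins <- as.integer(max_dist %/% map$resolution)
  surfs <- lapply(map_chroms(map), function(cn) {
    loop_stat_surface(map, expected, cn, max_dist_bins,
                      bg_outer = bg_outer, bg_inner = bg_inner,
                      pseudo_scale = pseudo_scale)
  })
  names(surfs) <- map_chroms(map)
  surfs
}

#' Call chromatin loops on a balanced contact map
#'
#' Candidate pixels (O/E >= `min_oe`, distance within `[min_dist,
#' max_dist]`, local `(2*bg_outer+1)^2` neighborhood not more than
#' `max_sparsity` zeros) are tested with an upper-tail Poisson probability
#' of the raw-equivalent observed count against the raw-rescaled local
#' background; p-values are BH-adjusted across all tested pixels and
#' significant 8-connected pixels are merged, keeping the strongest pixel
#' (highest observed, ties to the lexicographically smallest bin pair).
#'
#' @param map A balanced `contact_map`.
#' @param expected Its [compute_expected()] profile.
#' @param fdr BH false-discovery threshold (default 0.05).
#' @param min_dist,max_dist Anchor separation range in bp (defaults 50 kb
#'   and 2 Mb).
#' @param bg_outer,bg_inner Local background ring radii in bins (5 and 2).
#' @param max_sparsity Drop candidates whose local neighborhood has a
#'   larger zero fraction (default 0.8).
#' @param min_oe O/E pre-filter for candidate pixels (default 1.5).
#' @param sample_id Optional sample label attached to the calls.
#' @param pseudo_scale When the map carries no bias vector, balanced values
#'   are treated as pseudo-counts after division by this factor.
#' @param background_uncertainty Propagate the sampling variance of the
#'   neighborhood background estimate by using a gamma-Poisson (negative
#'   binomial) predictive tail instead of the plain Poisson tail (default
#'   TRUE). With an exactly known background the two coincide; with a
#'   noisily estimated one the plain Poisson tail is anti-conservative.
#' @return A loop tibble with `observed`, `expected_local`, `oe`,
#'   `p_value`, `q_value` (and `sample_id` when given).
#' @export
call_loops <- function(map, expected, fdr = 0.05,
                       min_dist = 5e4, max_dist = 2e6,
                       bg_outer = 5L, bg_inner = 2L,
                       max_sparsity = 0.8, min_oe = 1.5,
                       sample_id = NULL, pseudo_scale = 1,
                       background_uncertainty = TRUE) {
  surfs <- surface_for_map(map, expected, max_dist,
                           bg_outer = bg_outer, bg_inner = bg_inner,
                           pseudo_scale = pseudo_scale)
  res <- map$resolution
  min_d <- as.integer(ceiling(min_dist / res))
  cand <- purrr::map(surfs, function(sf) {
    D <- sf$dmax_test
    sel <- which(sf$V[, seq_len(D + 1L), drop = FALSE] &
                   sf$OE[, seq_len(D + 1L), drop = FALSE] >= min_oe &
                   sf$B[, seq_len(D + 1L), drop = FALSE] > 0,
                 arr.ind = TRUE)
    if (!nrow(sel)) return(NULL)
    i <- unname(sel[, 1]) - 1L; d <- unname(sel[, 2]) - 1L
    keep <- d >= min_d
    i <- i[keep]; d <- d[keep]
    if (!length(i)) return(NULL)
    idx <- cbind(i + 1L, d + 1L)
    lam <- sf$lambda_raw[idx]
    obs <- sf$raw_obs[idx]
    ok <- is.finite(lam) & lam > 0 & sf$zero_frac[idx] <= max_sparsity
    if (!any(ok)) return(NULL)
    size <- sf$bg_size[idx][ok]
    p <- background_tail(ceiling(obs[ok]) - 1, lam[ok], size,
                         background_uncertainty)
    tibble::tibble(chrom = sf$chrom, bin1 = i[ok], bin2 = (i + d)[ok],
                   observed = sf$B[idx][ok],
                   expected_local = sf$lambda_bal[idx][ok],
                   oe = sf$OE[idx][ok],
                   p_value = p)
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0L) return(annotate_calls(empty_calls(), res, sample_id))
  cand$q_value <- stats::p.adjust(cand$p_value, method = "BH")
  sig <- cand[cand$q_value <= fdr, , drop = FALSE]
  if (nrow(sig) == 0L) return(annotate_calls(empty_calls(), res, sample_id))
  picked <- dplyr::bind_rows(lapply(split(sig, sig$chrom), merge_adjacent))
  picked <- dplyr::arrange(picked, .data$chrom, .data$bin1, .data$bin2)
  annotate_calls(picked, res, sample_id)
}

# Upper-tail probability of observing > q counts under the estimated local
# background: Poisson when the background is taken as known, gamma-Poisson
# (negative binomial with the background estimator's effective shape) when
# its sampling variance is propagated.
background_tail <- function(q, lambda, size, background_uncertainty = TRUE) {
  if (!background_uncertainty) {
    return(stats::ppois(q, lambda, lower.tail = FALSE))
  }
  size <- pmax(size, 1e-8)
  ifelse(is.finite(size),
         stats::pnbinom(q, size = size, mu = lambda, lower.tail = FALSE),
         stats::ppois(q, lambda, lower.tail = FALSE))
}

empty_calls <- function() {
  tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                 observed = numeric(), expected_local = numeric(),
                 oe = numeric(), p_value = numeric(), q_value = numeric())
}

annotate_calls <- function(calls, resolution, sample_id) {
  out <- tibble::tibble(
    chrom1 = calls$chrom, start1 = calls$bin1 * resolution,
    end1 = (calls$bin1 + 1) * resolution,
    chrom2 = calls$chrom, start2 = calls$bin2 * resolution,
    end2 = (calls$bin2 + 1) * resolution,
    bin1 = calls$bin1, bin2 = calls$bin2,
    observed = calls$observed, expected_local = calls$expected_local,
    oe = calls$oe, p_value = calls$p_value, q_value = calls$q_value)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

# Union-find merge of 8-connected significant pixels; keep the strongest.
merge_adjacent <- function(px) {
  n <- nrow(px)
  if (n <= 1L) return(px)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  key <- function(i, j) paste(i, j)
  lookup <- stats::setNames(seq_len(n), key(px$bin1, px$bin2))
  for (k in seq_len(n)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      hit <- lookup[key(px$bin1[k] + di, px$bin2[k] + dj)]
      if (!is.na(hit)) {
        ra <- find(k); rb <- find(hit)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  picked <- vapply(split(seq_len(n), comp), function(idx) {
    sub <- px[idx, ]
    best <- which(sub$observed == max(sub$observed))
    if (length(best) > 1L) {
      best <- best[order(sub$bin1[best], sub$bin2[best])][1]
    }
    idx[best]
  }, 1L)
  px[sort(picked), , drop = FALSE]
}

#' Local loop statistics at arbitrary pixels
#'
#' Evaluates the same local-background operator as [call_loops()] at the
#' requested bin pairs.
#'
#' @param map A balanced `contact_map`.
#' @param expected Its expected profile.
#' @param anchors Tibble with `chrom`, `bin1`, `bin2`.
#' @param ... Passed to the surface construction (`bg_outer`, `bg_inner`,
#'   `pseudo_scale`).
#' @return A tibble with `observed`, `local_background`, `oe` and a
#'   `defined` flag (FALSE on masked bins or out-of-range pixels).
#' @export
pixel_stats <- function(map, expected, anchors, ...) {
  max_dist <- max((anchors$bin2 - anchors$bin1) * map$resolution,
                  map$resolution)
  surfs <- surface_for_map(map, expected, max_dist, ...)
  out <- purrr::map(seq_len(nrow(anchors)), function(k) {
    sf <- surfs[[anchors$chrom[k]]]
    i <- anchors$bin1[k]; d <- anchors$bin2[k] - anchors$bin1[k]
    if (is.null(sf) || i < 0 || d < 0 || d > sf$dmax ||
        i + 1L > sf$n || !sf$V[i + 1L, d + 1L]) {
      return(tibble::tibble(observed = NA_real_,
                            local_background = NA_real_,
                            oe = NA_real_, defined = FALSE))
    }
    tibble::tibble(observed = sf$B[i + 1L, d + 1L],
                   local_background = sf$lambda_bal[i + 1L, d + 1L],
                   oe = sf$OE[i + 1L, d + 1L], defined = TRUE)
  })
  dplyr::bind_rows(out)
}
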