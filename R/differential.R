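#' Match two loop lists by anchor proximity
#'
#' Greedy one-to-one matching: a pair is admissible when both anchors lie
#' within `tol_bins` bins; admissible pairs are taken in order of total
#' anchor offset, ties broken by the lexicographically smaller coordinates.
#'
#' @param a,b Loop tibbles with `chrom1`, `bin1`, `bin2`.
#' @param tol_bins Per-anchor matching tolerance in bins (default 1).
#' @return A tibble with `idx_a`, `idx_b`, `offset` (total bins).
#' @export
match_loops <- function(a, b, tol_bins = 1L) {
  empty <- tibble::tibble(idx_a = integer(), idx_b = integer(),
                          offset = integer())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  cand <- list()
  for (cn in intersect(unique(a$chrom1), unique(b$chrom1))) {
    ia <- which(a$chrom1 == cn); ib <- which(b$chrom1 == cn)
    d1 <- abs(outer(a$bin1[ia], b$bin1[ib], "-"))
    d2 <- abs(outer(a$bin2[ia], b$bin2[ib], "-"))
    hit <- which(d1 <= tol_bins & d2 <= tol_bins, arr.ind = TRUE)
    if (nrow(hit)) {
      cand[[cn]] <- tibble::tibble(idx_a = ia[hit[, 1]], idx_b = ib[hit[, 2]],
                                   offset = d1[hit] + d2[hit])
    }
  }
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0L) return(empty)
  ord <- order(cand$offset, a$bin1[cand$idx_a], a$bin2[cand$idx_a],
               b$bin1[cand$idx_b], b$bin2[cand$idx_b])
  cand <- cand[ord, ]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$idx_a[k]] && !used_b[cand$idx_b[k]]) {
      keep[k] <- TRUE
      used_a[cand$idx_a[k]] <- TRUE
      used_b[cand$idx_b[k]] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Loops enriched in one sample over another
#'
#' For each loop called in sample x (at `fdr_call`), the matched pixel in
#' sample y is the highest-O/E pixel within +/-1 bin; the two raw-equivalent
#' observed counts are compared with a conditional binomial rate test (the
#' exact two-sample Poisson test), one-sided toward x, with local
#' backgrounds as exposures. BH adjustment at `fdr_diff` plus an O/E ratio
#' floor gives the differential set.
#'
#' @param loops_x Loop calls in sample x (from [call_loops()]).
#' @param map_x,map_y Balanced maps of the two samples (same resolution).
#' @param expected_x,expected_y Their expected profiles.
#' @param fdr_diff Differential BH threshold (default 0.001).
#' @param min_ratio O/E ratio floor x over y (default 1.5).
#' @param fdr_call Call-level q filter applied to `loops_x` (default 0.05).
#' @param surface_x,surface_y Optional precomputed stat surfaces
#'   (recomputed when NULL); pass these when comparing many sample pairs.
#' @return The differential loop tibble (x coordinates) with `oe_x`,
#'   `oe_y`, `ratio`, `diff_p`, `diff_q`.
#' @export
pairwise_differential <- function(loops_x, map_x, map_y,
                                  expected_x, expected_y,
                                  fdr_diff = 0.001, min_ratio = 1.5,
                                  fdr_call = 0.05,
                                  surface_x = NULL, surface_y = NULL) {
  if (map_x$resolution != map_y$resolution) stop("resolution mismatch")
  if ("q_value" %in% names(loops_x)) {
    loops_x <- loops_x[loops_x$q_value <= fdr_call, , drop = FALSE]
  }
  if (nrow(loops_x) == 0L) return(loops_x)
  max_dist <- max((loops_x$bin2 - loops_x$bin1 + 2L) * map_x$resolution)
  if (is.null(surface_x)) {
    surface_x <- surface_for_map(map_x, expected_x, max_dist)
  }
  if (is.null(surface_y)) {
    surface_y <- surface_for_map(map_y, expected_y, max_dist)
  }
  stats_tbl <- purrr::map(seq_len(nrow(loops_x)), function(k) {
    cn <- loops_x$chrom1[k]
    sfx <- surface_x[[cn]]; sfy <- surface_y[[cn]]
    i <- loops_x$bin1[k]; j <- loops_x$bin2[k]
    ox <- sfx$raw_obs[i + 1L, j - i + 1L]
    lx <- sfx$lambda_raw[i + 1L, j - i + 1L]
    oex <- sfx$OE[i + 1L, j - i + 1L]
    # best matching pixel in y within +/-1 bin, by O/E
    best <- c(NA_real_, NA_real_, 0)
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj; dd <- jj - ii
      if (ii < 0 || dd < 0 || dd > sfy$dmax || ii + 1L > sfy$n) next
      if (!sfy$V[ii + 1L, dd + 1L]) next
      if (is.na(best[1]) || sfy$OE[ii + 1L, dd + 1L] > best[3]) {
        best <- c(sfy$raw_obs[ii + 1L, dd + 1L],
                  sfy$lambda_raw[ii + 1L, dd + 1L],
                  sfy$OE[ii + 1L, dd + 1L])
      }
    }
    tibble::tibble(ox = ox, lx = lx, oe_x = oex,
                   oy = best[1], ly = best[2], oe_y = best[3])
  })
  st <- dplyr::bind_rows(stats_tbl)
  ok <- is.finite(st$ox) & is.finite(st$oy) & is.finite(st$lx) &
    is.finite(st$ly) & (st$lx + st$ly) > 0
  loops_x <- loops_x[ok, , drop = FALSE]
  st <- st[ok, , drop = FALSE]
  if (nrow(st) == 0L) return(loops_x)
  total <- round(st$ox) + round(st$oy)
  pr <- st$lx / (st$lx + st$ly)
  p <- ifelse(total == 0, 1,
              stats::pbinom(round(st$ox) - 1, total, pr, lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  ratio <- st$oe_x / pmax(st$oe_y, 1e-12)
  out <- loops_x
  out$oe_x <- st$oe_x; out$oe_y <- st$oe_y; out$ratio <- ratio
  out$diff_p <- p; out$diff_q <- q
  out[q <= fdr_diff & ratio >= min_ratio, , drop = FALSE]
}

# Cluster loops across a named list of loop tables with tol_bins matching.
# Returns a membership tibble (cluster, source, chrom1, bin1, bin2).
cluster_loop_tables <- function(tables, tol_bins = 1L) {
  ref <- empty_cluster_ref()
  members <- list()
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0L) next
    tbl <- tbl[order(tbl$chrom1, tbl$bin1, tbl$bin2), , drop = FALSE]
    cl <- rep(NA_integer_, nrow(tbl))
    if (nrow(ref)) {
      mm <- match_loops(tbl, ref, tol_bins = tol_bins)
      cl[mm$idx_a] <- ref$cluster[mm$idx_b]
    }
    new <- which(is.na(cl))
    if (length(new)) {
      cl[new] <- max(0L, ref$cluster) + seq_along(new)
      ref <- dplyr::bind_rows(ref, tibble::tibble(
        chrom1 = tbl$chrom1[new], bin1 = tbl$bin1[new], bin2 = tbl$bin2[new],
        cluster = cl[new]))
    }
    members[[nm]] <- tibble::tibble(cluster = cl, source = nm,
                                    chrom1 = tbl$chrom1,
                                    bin1 = tbl$bin1, bin2 = tbl$bin2)
  }
  dplyr::bind_rows(members)
}

empty_cluster_ref <- function() {
  tibble::tibble(chrom1 = character(), bin1 = integer(), bin2 = integer(),
                 cluster = integer())
}

# Most frequent exact coordinates in a cluster; ties lexicographic smallest.
representative_coords <- function(members) {
  members |>
    dplyr::count(.data$cluster, .data$chrom1, .data$bin1, .data$bin2) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$n), .data$chrom1,
                   .data$bin1, .data$bin2) |>
    dplyr::distinct(.data$cluster, .keep_all = TRUE) |>
    dplyr::select(-"n")
}

#' Gained loops for one sample from its pairwise comparisons
#'
#' A loop is gained for a sample when, after cross-comparison matching, it
#' is differential in at least `min_pairwise` of the sample's comparisons
#' to the opposite group.
#'
#' @param pairwise Named list of [pairwise_differential()] results for this
#'   sample versus each opposite-group sample.
#' @param min_pairwise Minimum supporting comparisons (default 2).
#' @param tol_bins Matching tolerance in bins (default 1).
#' @return A loop tibble with `n_pairwise` and `comparisons` columns.
#' @export
gained_loops_for_sample <- function(pairwise, min_pairwise = 2L,
                                    tol_bins = 1L) {
  if (length(pairwise) == 0L) stop("no pairwise comparisons supplied")
  if (is.null(names(pairwise))) {
    names(pairwise) <- sprintf("cmp%d", seq_along(pairwise))
  }
  members <- cluster_loop_tables(pairwise, tol_bins = tol_bins)
  if (nrow(members) == 0L) {
    return(tibble::tibble(chrom1 = character(), bin1 = integer(),
                          bin2 = integer(), n_pairwise = integer(),
                          comparisons = character()))
  }
  support <- members |>
    dplyr::summarise(n_pairwise = dplyr::n_distinct(.data$source),
                     comparisons = paste(sort(unique(.data$source)),
                                         collapse = ","),
                     .by = "cluster")
  rep_coords <- representative_coords(members)
  out <- dplyr::inner_join(rep_coords, support, by = "cluster") |>
    dplyr::filter(.data$n_pairwise >= min_pairwise) |>
    dplyr::arrange(.data$chrom1, .data$bin1, .data$bin2) |>
    dplyr::select(-"cluster")
  out
}

#' Subtype-enriched consensus loops
#'
#' Second consensus level: loops gained in at least `min_samples` samples
#' of a group are reported once, with a representative coordinate (most
#' frequent exact coordinates across supporting samples, ties to the
#' lexicographically smallest) and full per-sample provenance.
#'
#' @param per_sample_gained Named list (sample id -> gained-loop tibble
#'   from [gained_loops_for_sample()]).
#' @param group Group label for the report.
#' @param min_samples Minimum supporting samples (default 2).
#' @param tol_bins Matching tolerance in bins (default 1).
#' @param resolution Bin size in bp used to emit anchor coordinates.
#' @return A `consensus_report` object; `tidy()` returns the loop table,
#'   `glance()` the counts and thresholds.
#' @export
subtype_enriched_loops <- function(per_sample_gained, group = "A",
                                   min_samples = 2L, tol_bins = 1L,
                                   resolution = NULL) {
  if (length(per_sample_gained) < min_samples) {
    stop("group has fewer samples (", length(per_sample_gained),
         ") than min_samples (", min_samples, ")")
  }
  members <- cluster_loop_tables(per_sample_gained, tol_bins = tol_bins)
  if (nrow(members)) {
    support <- members |>
      dplyr::summarise(n_samples = dplyr::n_distinct(.data$source),
                       samples = paste(sort(unique(.data$source)),
                                       collapse = ","),
                       .by = "cluster")
    loops <- dplyr::inner_join(representative_coords(members), support,
                               by = "cluster") |>
      dplyr::filter(.data$n_samples >= min_samples) |>
      dplyr::arrange(.data$chrom1, .data$bin1, .data$bin2) |>
      dplyr::select(-"cluster")
  } else {
    loops <- tibble::tibble(chrom1 = character(), bin1 = integer(),
                            bin2 = integer(), n_samples = integer(),
                            samples = character())
  }
  if (!is.null(resolution)) {
    loops <- dplyr::mutate(loops,
                           start1 = .data$bin1 * resolution,
                           end1 = (.data$bin1 + 1) * resolution,
                           chrom2 = .data$chrom1,
                           start2 = .data$bin2 * resolution,
                           end2 = (.data$bin2 + 1) * resolution,
                           .after = "chrom1")
  }
  structure(list(group = group, loops = loops,
                 thresholds = list(min_samples = min_samples,
                                   tol_bins = tol_bins)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> group %s: %d subtype-enriched loops (>= %d samples)\n",
              x$group, nrow(x$loops), x$thresholds$min_samples))
  invisible(x)
}

#' @export
tidy.consensus_report <- function(x, ...) x$loops

#' @export
glance.consensus_report <- function(x, ...) {
  tibble::tibble(group = x$group, n_loops = nrow(x$loops),
                 min_samples = x$thresholds$min_samples,
                 tol_bins = x$thresholds$tol_bins)
}
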