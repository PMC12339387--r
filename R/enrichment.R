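loop_anchor_table <- function(loops) {
  tibble::tibble(loop = rep(seq_len(nrow(loops)), 2L),
                 chrom = c(loops$chrom1, loops$chrom2),
                 start = c(loops$start1, loops$start2),
                 end = c(loops$end1, loops$end2))
}

#' Fraction of loops with an anchor overlapping a CRE set
#'
#' A loop counts as overlapping when anchor1 or anchor2 shares at least
#' one bp with at least one CRE interval (either-anchor rule).
#'
#' @param loops Loop tibble with bp anchor coordinates.
#' @param cres Interval tibble (`chrom`, `start`, `end`).
#' @return The observed loop-level overlap fraction in `[0, 1]`.
#' @export
anchor_cre_overlap <- function(loops, cres) {
  if (nrow(loops) == 0L) return(0)
  anchors <- loop_anchor_table(loops)
  hit <- overlaps_any_intervals(anchors, cres)
  mean(tapply(hit, anchors$loop, any))
}

#' Permutation test of loop-anchor CRE enrichment
#'
#' Each randomization replaces every anchor with a uniformly placed
#' interval of identical width on the same chromosome (loop pairing
#' preserved) and recomputes the overlap fraction. The empirical one-sided
#' p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param loops Loop tibble.
#' @param cres Interval tibble.
#' @param genome An `ld_genome` providing chromosome lengths.
#' @param n_perm Number of randomizations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @return An `enrichment_result` with `observed_fraction`,
#'   `null_fractions`, `p_empirical`; see `tidy()`/`glance()`.
#' @export
permutation_enrichment <- function(loops, cres, genome, n_perm = 1000L,
                                   seed = 1L) {
  stopifnot(n_perm >= 1L)
  observed <- anchor_cre_overlap(loops, cres)
  anchors <- loop_anchor_table(loops)
  width <- anchors$end - anchors$start
  clen <- chrom_length(genome, anchors$chrom)
  if (any(width > clen)) stop("anchor wider than its chromosome")
  n_anchor <- nrow(anchors)
  withr::local_seed(seed)
  null_fractions <- numeric(n_perm)
  if (n_anchor > 0L) {
    # one big uniform draw: n_perm replicates of every anchor
    st <- floor(stats::runif(n_anchor * n_perm) * rep(clen - width, n_perm))
    perm_anchors <- tibble::tibble(
      chrom = rep(anchors$chrom, n_perm),
      start = st, end = st + rep(width, n_perm))
    hit <- overlaps_any_intervals(perm_anchors, cres)
    perm_id <- rep(seq_len(n_perm), each = n_anchor)
    loop_id <- rep(anchors$loop, n_perm)
    loop_hit <- tapply(hit, list(perm_id, loop_id), any)
    null_fractions <- rowMeans(loop_hit)
  }
  p <- (1 + sum(null_fractions >= observed)) / (n_perm + 1)
  structure(list(observed_fraction = observed,
                 null_fractions = unname(null_fractions),
                 p_empirical = p, n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed %.3f | null mean %.3f | p = %.4g (%d perms)\n",
              x$observed_fraction, mean(x$null_fractions), x$p_empirical,
              x$n_perm))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_fractions),
                 null_fraction = x$null_fractions)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(observed_fraction = x$observed_fraction,
                 null_mean = mean(x$null_fractions),
                 p_empirical = x$p_empirical, n_perm = x$n_perm,
                 seed = x$seed)
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_fraction,
                        color = "red", linewidth = 1) +
    ggplot2::labs(x = "null overlap fraction", y = "permutations",
                  title = sprintf("observed %.3f, p = %.4g",
                                  object$observed_fraction,
                                  object$p_empirical)) +
    ggplot2::theme_minimal()
}

#' Link genes to loop anchors
#'
#' A gene is linked to a loop when its body, extended by `flank` bp on both
#' sides, shares at least one bp with either anchor.
#'
#' @param loops Loop tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param flank Extension in bp (default 3000).
#' @param tss_only Link on the transcription start site (strand-aware,
#'   extended by `flank`) instead of the gene body (default FALSE).
#' @return A tibble with one row per (gene, loop) link: `gene_id`,
#'   `loop_idx` (row in `loops`), anchor coordinates.
#' @export
link_genes <- function(loops, genes, flank = 3000, tss_only = FALSE) {
  empty <- tibble::tibble(gene_id = character(), loop_idx = integer())
  if (nrow(loops) == 0L || nrow(genes) == 0L) return(empty)
  if (tss_only) {
    tss <- ifelse(!is.null(genes$strand) & genes$strand == "-",
                  genes$end - 1, genes$start)
    q <- tibble::tibble(chrom = genes$chrom,
                        start = pmax(0, tss - flank), end = tss + 1 + flank)
  } else {
    q <- tibble::tibble(chrom = genes$chrom,
                        start = pmax(0, genes$start - flank),
                        end = genes$end + flank)
  }
  anchors <- loop_anchor_table(loops)
  out <- list()
  for (cn in unique(q$chrom)) {
    gi <- which(q$chrom == cn)
    ai <- which(anchors$chrom == cn)
    if (!length(ai)) next
    qr <- IRanges::IRanges(q$start[gi] + 1L, q$end[gi])
    sr <- IRanges::IRanges(anchors$start[ai] + 1L, anchors$end[ai])
    ov <- IRanges::findOverlaps(qr, sr)
    if (!length(ov)) next
    out[[cn]] <- tibble::tibble(
      gene_id = genes$gene_id[gi[S4Vectors::queryHits(ov)]],
      loop_idx = anchors$loop[ai[S4Vectors::subjectHits(ov)]])
  }
  links <- dplyr::bind_rows(out)
  if (nrow(links) == 0L) return(empty)
  dplyr::distinct(links) |> dplyr::arrange(.data$gene_id, .data$loop_idx)
}

#' Differential expression between two sample groups (t test on FPKM)
#'
#' Per gene: `log2FC = log2((mean_A + eps) / (mean_B + eps))` and a
#' two-sided two-sample t test on the FPKM values; a gene is significant
#' when `p < p_thresh` and `|log2FC| >= lfc_thresh`.
#'
#' @param expr Expression tibble (`gene_id` + one column per sample, FPKM).
#' @param labels Tibble (`sample`, `group`).
#' @param group_a,group_b The two group labels to contrast (A over B).
#' @param p_thresh,lfc_thresh Significance thresholds (defaults 0.05 and 1).
#' @param eps Pseudo-FPKM for fold-change stability (default 0.1).
#' @return A `deg_table` tibble: `gene_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `p_value`, `significant`.
#' @export
differential_expression <- function(expr, labels, group_a = "A",
                                    group_b = "B", p_thresh = 0.05,
                                    lfc_thresh = 1, eps = 0.1) {
  sa <- labels$sample[labels$group == group_a]
  sb <- labels$sample[labels$group == group_b]
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("need at least two samples per group")
  }
  A <- as.matrix(expr[, sa, drop = FALSE])
  B <- as.matrix(expr[, sb, drop = FALSE])
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df = na + nb - 2), 1)
  lfc <- log2((ma + eps) / (mb + eps))
  out <- tibble::tibble(gene_id = expr$gene_id, mean_a = ma, mean_b = mb,
                        log2fc = lfc, t_statistic = t_stat, p_value = p,
                        significant = p < p_thresh & abs(lfc) >= lfc_thresh)
  class(out) <- c("deg_table", class(out))
  out
}

#' Keep loops anchored by every required TF peak set
#'
#' A loop is kept when each required peak set intersects at least one of
#' its anchors (per-set either-anchor rule by default; `both_anchors`
#' requires every set to hit both anchors). Loops matching the exclusion
#' list within `tol_bins` are then removed.
#'
#' @param loops Loop tibble with `bin1`, `bin2` and bp coordinates.
#' @param required_peaks List of interval tibbles that must all hit the
#'   loop.
#' @param exclude_loops Optional loop tibble to subtract (matched with
#'   [match_loops()]).
#' @param tol_bins Exclusion matching tolerance (default 1).
#' @param both_anchors Require each peak set at both anchors
#'   (default FALSE).
#' @return The filtered loop tibble.
#' @export
annotate_tf_anchored <- function(loops, required_peaks,
                                 exclude_loops = NULL, tol_bins = 1L,
                                 both_anchors = FALSE) {
  if (nrow(loops) == 0L) return(loops)
  keep <- rep(TRUE, nrow(loops))
  a1 <- tibble::tibble(chrom = loops$chrom1, start = loops$start1,
                       end = loops$end1)
  a2 <- tibble::tibble(chrom = loops$chrom2, start = loops$start2,
                       end = loops$end2)
  for (peaks in required_peaks) {
    h1 <- overlaps_any_intervals(a1, peaks)
    h2 <- overlaps_any_intervals(a2, peaks)
    keep <- keep & if (both_anchors) h1 & h2 else h1 | h2
  }
  out <- loops[keep, , drop = FALSE]
  if (!is.null(exclude_loops) && nrow(exclude_loops) && nrow(out)) {
    mm <- match_loops(out, exclude_loops, tol_bins = tol_bins)
    if (nrow(mm)) out <- out[-mm$idx_a, , drop = FALSE]
  }
  out
}
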