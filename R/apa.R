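#' Aggregate peak analysis pileup
#'
#' Extracts the `window_bins` x `window_bins` observed/expected submatrix
#' centered on each loop pixel and averages element-wise over loops. Loops
#' whose window crosses a chromosome edge, touches the diagonal (any cell
#' with `bin_i >= bin_j`) or overlaps a masked bin are skipped and counted
#' in `n_skipped`. At 10 kb resolution the default window of 5 bins is a
#' 50 kb x 50 kb matrix.
#'
#' @param map A balanced `contact_map`.
#' @param expected Its expected profile.
#' @param loops Loop tibble with `chrom1`, `bin1`, `bin2` (bin coordinates
#'   at map resolution; see [loops_to_bins()] for external BEDPE).
#' @param window_bins Odd window size in bins (default 5).
#' @return An `apa_pileup` object with the mean O/E `matrix`, `apa_score`
#'   (mean of the central 3x3), `n_used` and `n_skipped`.
#' @export
pileup <- function(map, expected, loops, window_bins = 5L) {
  window_bins <- as.integer(window_bins)
  if (window_bins %% 2L == 0L) stop("window_bins must be odd")
  if (!map$balanced) stop("pileup requires a balanced map")
  h <- window_bins %/% 2L
  acc <- matrix(0, window_bins, window_bins)
  n_used <- 0L; n_skipped <- 0L
  for (cn in unique(loops$chrom1)) {
    sub <- loops[loops$chrom1 == cn, , drop = FALSE]
    n <- n_bins(map$genome, cn, map$resolution)
    dmax <- min(max(sub$bin2 - sub$bin1) + 2L * h, n - 1L)
    B <- band_matrix(map, cn, dmax)
    V <- band_valid(map, cn, dmax)
    e <- expected_vector(expected, cn, dmax)
    OE <- sweep(B, 2, e, "/")
    OE[!V | !is.finite(OE)] <- 0
    m <- chrom_mask(map, cn)
    for (k in seq_len(nrow(sub))) {
      i <- sub$bin1[k]; j <- sub$bin2[k]
      ii <- (i - h):(i + h); jj <- (j - h):(j + h)
      if (min(ii) < 0L || max(jj) >= n || (j - h) - (i + h) <= 0L ||
          !all(m[ii + 1L]) || !all(m[jj + 1L])) {
        n_skipped <- n_skipped + 1L
        next
      }
      W <- matrix(0, window_bins, window_bins)
      for (a in seq_len(window_bins)) {
        W[a, ] <- OE[ii[a] + 1L, jj - ii[a] + 1L]
      }
      acc <- acc + W
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no usable loops for pileup")
  mat <- acc / n_used
  structure(list(matrix = mat, window_bins = window_bins,
                 apa_score = apa_score_matrix(mat),
                 n_used = n_used, n_skipped = n_skipped,
                 resolution = map$resolution),
            class = "apa_pileup")
}

apa_score_matrix <- function(mat) {
  c0 <- (nrow(mat) + 1L) %/% 2L
  mean(mat[(c0 - 1L):(c0 + 1L), (c0 - 1L):(c0 + 1L)])
}

#' APA score of a pileup
#'
#' The arithmetic mean of the central 3 x 3 square of the pileup matrix.
#'
#' @param pileup An `apa_pileup` (or a plain square matrix).
#' @return The APA score.
#' @export
apa_score <- function(pileup) {
  mat <- if (inherits(pileup, "apa_pileup")) pileup$matrix else pileup
  if (nrow(mat) < 3L) stop("window must be at least 3 bins for an APA score")
  apa_score_matrix(mat)
}

#' @export
print.apa_pileup <- function(x, ...) {
  cat(sprintf("<apa_pileup> %dx%d window | APA score %.3f | %d loops used, %d skipped\n",
              x$window_bins, x$window_bins, x$apa_score, x$n_used, x$n_skipped))
  invisible(x)
}

#' @export
tidy.apa_pileup <- function(x, ...) {
  h <- x$window_bins %/% 2L
  tibble::tibble(dx = rep(-h:h, times = x$window_bins),
                 dy = rep(-h:h, each = x$window_bins),
                 oe = as.vector(x$matrix))
}

#' @export
glance.apa_pileup <- function(x, ...) {
  tibble::tibble(apa_score = x$apa_score, window_bins = x$window_bins,
                 n_used = x$n_used, n_skipped = x$n_skipped)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.apa_pileup <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dx, y = .data$dy,
                                   fill = log2(pmax(.data$oe, 1e-3)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "log2 O/E") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset (bins)", y = "offset (bins)",
                  title = sprintf("APA score %.2f (n = %d)",
                                  object$apa_score, object$n_used)) +
    ggplot2::theme_minimal()
}

#' Compare APA scores between two sample groups
#'
#' Two-sample pooled-variance (Student's) t test, one-sided by default;
#' Welch's form is available by flag. When both groups are constant and
#' equal the test statistic is 0 and the one-sided p is 0.5 by convention.
#'
#' @param scores_a,scores_b Numeric APA scores (>= 2 each).
#' @param alternative "greater" (a > b), "less" or "two.sided".
#' @param var_equal Use the pooled-variance form (default TRUE).
#' @return A tibble with `statistic`, `df`, `p_value`, group means.
#' @export
compare_apa_groups <- function(scores_a, scores_b,
                               alternative = c("greater", "less", "two.sided"),
                               var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("need at least two APA scores per group")
  }
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    delta <- mean(scores_a) - mean(scores_b)
    p <- switch(alternative,
                greater = if (delta > 0) 0 else if (delta < 0) 1 else 0.5,
                less = if (delta < 0) 0 else if (delta > 0) 1 else 0.5,
                two.sided = if (delta == 0) 1 else 0)
    return(tibble::tibble(statistic = if (delta == 0) 0 else Inf * sign(delta),
                          df = length(scores_a) + length(scores_b) - 2,
                          p_value = p, mean_a = mean(scores_a),
                          mean_b = mean(scores_b)))
  }
  tt <- stats::t.test(scores_a, scores_b, alternative = alternative,
                      var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_a = mean(scores_a),
                 mean_b = mean(scores_b))
}

#' Convert bp loop coordinates to bin coordinates
#'
#' @param loops Loop tibble with `start1`, `start2`.
#' @param resolution Bin size in bp.
#' @return The loops with `bin1`, `bin2` columns added.
#' @export
loops_to_bins <- function(loops, resolution) {
  dplyr::mutate(loops,
                bin1 = as.integer(.data$start1 %/% resolution),
                bin2 = as.integer(.data$start2 %/% resolution))
}
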