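#' Configuration for the synthetic two-group Hi-C cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: ICE-balanceable cis maps with power-law distance decay and
#' Poisson pixel counts, planted shared and group-specific loops as focal
#' multiplicative enrichments, a 100-kb compartment checkerboard that
#' partially differs between groups, CRE sets concentrated at group-specific
#' anchors, and FPKM expression tables where loop-linked genes carry a set
#' log2 fold-change.
#'
#' @param seed Integer root seed; the full cohort is reproducible from it.
#' @param n_group_a,n_group_b Samples per group (default 4 vs 4).
#' @param chrom Chromosome name of the single simulated chromosome.
#' @param chrom_length Chromosome length in bp (default 50 Mb).
#' @param resolution Map bin size in bp (default 10 kb).
#' @param decay_exponent Power-law exponent `alpha` of the distance decay
#'   `(d+1)^-alpha` (default 1, the canonical Hi-C contact-probability
#'   scaling).
#' @param depth Expected total cis pair count per sample (default 1e7).
#' @param loop_enrichment Multiplicative factor `phi >= 1` applied to the
#'   Poisson mean at planted loop pixels (default 8).
#' @param loop_spill Gaussian spread `sigma` of the loop enrichment in bins
#'   (default 0.5: focal, essentially one-pixel loops).
#' @param n_shared,n_a_specific,n_b_specific Planted loop counts per class.
#' @param min_span,max_span Loop anchor separation range in bp
#'   (default 200 kb to 1 Mb, enhancer--promoter scale).
#' @param compartment_block_size Compartment block granularity in bp
#'   (default 100 kb).
#' @param compartment_strength O/E contrast of the compartment checkerboard:
#'   same-label bin pairs get this factor, opposite-label pairs its
#'   reciprocal (default 1.6).
#' @param comp_flip_frac Fraction of compartment blocks whose label is
#'   flipped in group B relative to group A (default 0.2); this is what
#'   makes eigenvector tracks cluster by group.
#' @param expr_effect log2 fold-change added, in its own group, to genes
#'   linked to group-specific loop anchors (default 2).
#' @param expr_noise_sd SD of i.i.d. Gaussian log2 expression noise
#'   (default 0.25).
#' @param cre_signal_frac Fraction of each group's CREs centered on that
#'   group's specific anchors; the rest are uniform (default 0.5).
#' @param n_cres CREs per group set (default 200).
#' @param n_genes Genes in the synthetic annotation (default 400).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_group_a = 4L, n_group_b = 4L,
                          chrom = "chrS", chrom_length = 5e7,
                          resolution = 1e4,
                          decay_exponent = 1,
                          depth = 1e7,
                          loop_enrichment = 8,
                          loop_spill = 0.5,
                          n_shared = 40L, n_a_specific = 30L,
                          n_b_specific = 30L,
                          min_span = 2e5, max_span = 1e6,
                          compartment_block_size = 1e5,
                          compartment_strength = 1.6,
                          comp_flip_frac = 0.2,
                          expr_effect = 2,
                          expr_noise_sd = 0.25,
                          cre_signal_frac = 0.5,
                          n_cres = 200L,
                          n_genes = 400L) {
  cfg <- list(seed = as.integer(seed), n_group_a = as.integer(n_group_a),
              n_group_b = as.integer(n_group_b), chrom = chrom,
              chrom_length = chrom_length, resolution = resolution,
              decay_exponent = decay_exponent, depth = depth,
              loop_enrichment = loop_enrichment, loop_spill = loop_spill,
              n_shared = as.integer(n_shared),
              n_a_specific = as.integer(n_a_specific),
              n_b_specific = as.integer(n_b_specific),
              min_span = min_span, max_span = max_span,
              compartment_block_size = compartment_block_size,
              compartment_strength = compartment_strength,
              comp_flip_frac = comp_flip_frac,
              expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
              cre_signal_frac = cre_signal_frac, n_cres = as.integer(n_cres),
              n_genes = as.integer(n_genes))
  stopifnot(cfg$n_group_a >= 0, cfg$n_group_b >= 0,
            cfg$decay_exponent > 0, cfg$depth >= 0,
            cfg$loop_enrichment >= 1, cfg$loop_spill > 0,
            cfg$n_shared >= 0, cfg$n_a_specific >= 0, cfg$n_b_specific >= 0,
            cfg$min_span >= cfg$resolution, cfg$max_span >= cfg$min_span,
            cfg$compartment_strength >= 1,
            cfg$comp_flip_frac >= 0, cfg$comp_flip_frac <= 1,
            cfg$cre_signal_frac >= 0, cfg$cre_signal_frac <= 1,
            cfg$expr_noise_sd > 0)
  class(cfg) <- "cohort_config"
  cfg
}

sim_genome <- function(config) genome_def(config$chrom, config$chrom_length)

# Minimum Chebyshev pixel separation between planted loops; keeps every
# loop's detection/APA window free of other planted signal.
LOOP_SEP_BINS <- 12L

#' Plant the cohort ground truth
#'
#' Places shared, A-specific and B-specific loops without collision
#' (pairwise Chebyshev pixel distance > the APA/detection window) and draws
#' compartment block labels for both groups.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_truth` list with `loops` (tibble: `loop_id`, `chrom`,
#'   `bin1`, `bin2`, coordinates and `class`), `blocks` (compartment block
#'   labels per group) and the per-bin label vectors.
#' @export
simulate_truth <- function(config) {
  withr::local_seed(config$seed)
  res <- config$resolution
  n <- as.integer(ceiling(config$chrom_length / res))
  bins_per_block <- as.integer(config$compartment_block_size %/% res)
  n_blocks <- as.integer(ceiling(n / bins_per_block))
  lab_a <- sample(c(-1L, 1L), n_blocks, replace = TRUE)
  n_flip <- round(config$comp_flip_frac * n_blocks)
  flip <- if (n_flip > 0) sample.int(n_blocks, n_flip) else integer()
  lab_b <- lab_a
  lab_b[flip] <- -lab_b[flip]
  blocks <- tibble::tibble(
    block = seq_len(n_blocks),
    start = (seq_len(n_blocks) - 1) * config$compartment_block_size,
    end = pmin(seq_len(n_blocks) * config$compartment_block_size,
               config$chrom_length),
    label_a = lab_a, label_b = lab_b)
  bin_block <- pmin((seq_len(n) - 1L) %/% bins_per_block + 1L, n_blocks)

  n_total <- config$n_shared + config$n_a_specific + config$n_b_specific
  min_bins <- as.integer(config$min_span %/% res)
  max_bins <- as.integer(config$max_span %/% res)
  margin <- LOOP_SEP_BINS
  if (n - max_bins - 2L * margin < n_total) {
    stop("chromosome too short to place the requested loops")
  }
  # Loop anchors are restricted to active (label +1) compartment blocks
  # whose label is identical in both groups, mirroring the predominance of
  # enhancer-promoter loops inside the A compartment. This also makes
  # "shared" mean exactly that: identical expected contact in both groups.
  anchor_ok <- lab_a[bin_block] == 1L & lab_b[bin_block] == 1L
  if (!any(anchor_ok) || config$compartment_strength == 1) {
    anchor_ok <- rep(TRUE, n)
  }
  b1 <- integer(n_total); b2 <- integer(n_total)
  placed <- 0L; tries <- 0L
  while (placed < n_total) {
    tries <- tries + 1L
    if (tries > 2000L * n_total) {
      stop("could not place ", n_total, " non-colliding loops")
    }
    span <- sample(min_bins:max_bins, 1L)
    i <- sample(margin:(n - span - margin), 1L)
    j <- i + span
    if (!anchor_ok[i + 1L] || !anchor_ok[j + 1L]) next
    if (placed > 0L) {
      cheb <- pmax(abs(b1[seq_len(placed)] - i), abs(b2[seq_len(placed)] - j))
      if (min(cheb) <= LOOP_SEP_BINS) next
    }
    placed <- placed + 1L
    b1[placed] <- i; b2[placed] <- j
  }
  cls <- c(rep("shared", config$n_shared),
           rep("A_specific", config$n_a_specific),
           rep("B_specific", config$n_b_specific))
  loops <- tibble::tibble(
    loop_id = sprintf("L%03d", seq_len(n_total)),
    chrom = config$chrom, bin1 = b1, bin2 = b2,
    start1 = b1 * res, end1 = (b1 + 1) * res,
    start2 = b2 * res, end2 = (b2 + 1) * res,
    class = cls)
  structure(list(loops = loops, blocks = blocks,
                 bin_label_a = lab_a[bin_block], bin_label_b = lab_b[bin_block],
                 n_bins = n, bins_per_block = bins_per_block),
            class = "cohort_truth")
}

truth_bin_labels <- function(truth, group) {
  if (group == "A") truth$bin_label_a else truth$bin_label_b
}

loop_classes_for_group <- function(group) {
  c("shared", paste0(group, "_specific"))
}

# Gaussian spill factors around each planted loop pixel for one group:
# tibble(bin1, bin2, factor) with factor = 1 + (phi-1) exp(-r^2 / (2 sigma^2)).
loop_factor_table <- function(config, truth, group) {
  loops <- truth$loops[truth$loops$class %in% loop_classes_for_group(group), ]
  if (nrow(loops) == 0L) {
    return(tibble::tibble(bin1 = integer(), bin2 = integer(),
                          factor = numeric()))
  }
  r <- max(1L, as.integer(ceiling(3 * config$loop_spill)))
  off <- expand.grid(di = -r:r, dj = -r:r)
  fac <- 1 + (config$loop_enrichment - 1) *
    exp(-(off$di^2 + off$dj^2) / (2 * config$loop_spill^2))
  keep <- fac > 1 + 1e-6
  off <- off[keep, ]; fac <- fac[keep]
  tbl <- tibble::tibble(
    bin1 = rep(loops$bin1, each = nrow(off)) + rep(off$di, nrow(loops)),
    bin2 = rep(loops$bin2, each = nrow(off)) + rep(off$dj, nrow(loops)),
    factor = rep(fac, nrow(loops)))
  tbl <- tbl[tbl$bin1 >= 0 & tbl$bin2 < truth$n_bins &
               tbl$bin1 <= tbl$bin2, ]
  dplyr::summarise(tbl, factor = max(.data$factor), .by = c("bin1", "bin2"))
}

#' Simulate one sample's contact map
#'
#' Pixel counts are independent Poisson draws with mean
#' `lambda_ij = depth * Z^-1 * (|i-j|+1)^-alpha * B_ij * C_ij`, where `B`
#' is the planted-loop enrichment (for this group's shared + own-specific
#' loops, spread by `loop_spill`), `C` the compartment checkerboard factor,
#' and `Z` normalises the total expectation to `depth`.
#'
#' @param config A [cohort_config()].
#' @param truth A [simulate_truth()] result consistent with `config`.
#' @param group `"A"` or `"B"`.
#' @param sample_seed Integer seed for this sample's Poisson draws.
#' @return A raw `contact_map`.
#' @export
simulate_contact_map <- function(config, truth, group, sample_seed) {
  stopifnot(group %in% c("A", "B"))
  n <- truth$n_bins
  lab <- truth_bin_labels(truth, group)
  s <- config$compartment_strength
  alpha <- config$decay_exponent
  lf <- loop_factor_table(config, truth, group)
  base <- (1:n)^(-alpha)              # base[d+1] = (d+1)^-alpha
  comp_lut <- c(1 / s, s)             # index by (label product + 3) / 2

  # Full upper triangle laid out distance-major: all pixels at d = 0, then
  # d = 1, ... One vectorised pass builds the unnormalised intensity, its
  # sum gives Z, and a single rpois draw realises the map.
  block_len <- n - 0:(n - 1L)
  d_vec <- rep.int(0:(n - 1L), block_len)
  i_vec <- sequence(block_len) - 1L
  lam0 <- base[d_vec + 1L] *
    comp_lut[(lab[i_vec + 1L] * lab[i_vec + d_vec + 1L] + 3L) %/% 2L]
  if (nrow(lf)) {
    offs <- c(0, cumsum(as.numeric(block_len)))
    pos <- offs[lf$bin2 - lf$bin1 + 1L] + lf$bin1 + 1
    lam0[pos] <- lam0[pos] * lf$factor
  }
  z <- sum(lam0)
  lam <- if (z > 0) (config$depth / z) * lam0 else 0 * lam0
  withr::local_seed(sample_seed)
  cnt <- stats::rpois(length(lam), lam)
  nz <- which(cnt > 0L)
  px <- tibble::tibble(chrom = rep(config$chrom, length(nz)),
                       bin1 = i_vec[nz], bin2 = i_vec[nz] + d_vec[nz],
                       count = as.numeric(cnt[nz]))
  contact_map(px, sim_genome(config), config$resolution, balanced = FALSE)
}

#' Simulate the full two-group cohort of contact maps
#'
#' Per-sample seeds are derived deterministically from `config$seed`, so
#' the whole cohort is reproducible from the root seed alone.
#'
#' @param config A [cohort_config()].
#' @return A list with `maps` (named list of raw `contact_map`s), `labels`
#'   (tibble `sample`, `group`) and `truth` (the [simulate_truth()] result).
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  n_samples <- config$n_group_a + config$n_group_b
  sample_ids <- c(sprintf("A%d", seq_len(config$n_group_a)),
                  sprintf("B%d", seq_len(config$n_group_b)))
  groups <- c(rep("A", config$n_group_a), rep("B", config$n_group_b))
  seeds <- withr::with_seed(config$seed,
                            sample.int(2147483646L, n_samples))
  maps <- purrr::map(seq_len(n_samples), function(k) {
    simulate_contact_map(config, truth, groups[k], seeds[k])
  })
  names(maps) <- sample_ids
  list(maps = maps,
       labels = tibble::tibble(sample = sample_ids, group = groups),
       truth = truth)
}

#' Synthetic gene annotation for the simulated chromosome
#'
#' Uniformly placed, non-overlapping genes of 5--50 kb.
#'
#' @param config A [cohort_config()].
#' @return A gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
simulate_genes <- function(config) {
  withr::local_seed(config$seed + 7919L)
  n <- config$n_genes
  width <- round(stats::runif(n, 5e3, 5e4))
  start <- sort(round(stats::runif(n, 0, config$chrom_length - max(width))))
  # nudge overlapping genes apart; drop any that would fall off the end
  for (k in seq_len(n)[-1]) {
    if (start[k] < start[k - 1] + width[k - 1] + 1e3) {
      start[k] <- start[k - 1] + width[k - 1] + 1e3
    }
  }
  end <- start + width
  keep <- end <= config$chrom_length
  tibble::tibble(gene_id = sprintf("G%04d", seq_len(sum(keep))),
                 chrom = config$chrom, start = start[keep],
                 end = end[keep],
                 strand = sample(c("+", "-"), sum(keep), replace = TRUE))
}

#' Simulate expression and CRE sets matched to the planted loops
#'
#' Genes within +/-3 kb of a group-specific loop anchor receive a
#' `expr_effect` log2 mean shift in that group; all genes get i.i.d.
#' Gaussian log2 noise and are back-transformed to FPKM. Each group's CRE
#' set places `cre_signal_frac` of its intervals centered on that group's
#' specific anchors, the rest uniformly.
#'
#' @param config A [cohort_config()].
#' @param truth A [simulate_truth()] result.
#' @param genes Gene annotation tibble; default [simulate_genes()].
#' @return A list: `expr` (tibble `gene_id` + sample columns, FPKM),
#'   `labels`, `genes` (with `linked_class` column), `cres` (list of
#'   interval tibbles `A`, `B`) and `phasing` (bedGraph-style tibble at
#'   compartment resolution).
#' @export
simulate_expression_and_cres <- function(config, truth,
                                         genes = simulate_genes(config)) {
  withr::local_seed(config$seed + 104729L)
  res <- config$resolution
  flank <- 3e3

  anchor_intervals <- function(classes) {
    lp <- truth$loops[truth$loops$class %in% classes, ]
    tibble::tibble(chrom = rep(lp$chrom, 2L),
                   start = c(lp$start1, lp$start2),
                   end = c(lp$end1, lp$end2))
  }
  linked_class <- rep("none", nrow(genes))
  ext <- dplyr::mutate(genes, start = pmax(0, .data$start - flank),
                       end = .data$end + flank)
  for (cl in c("A_specific", "B_specific")) {
    hit <- overlaps_any_intervals(ext, anchor_intervals(cl))
    linked_class[hit & linked_class == "none"] <- cl
  }
  genes$linked_class <- linked_class

  n_a <- config$n_group_a; n_b <- config$n_group_b
  sample_ids <- c(sprintf("A%d", seq_len(n_a)), sprintf("B%d", seq_len(n_b)))
  groups <- c(rep("A", n_a), rep("B", n_b))
  base <- stats::rnorm(nrow(genes), mean = 5, sd = 1)
  shift <- cbind(A = ifelse(linked_class == "A_specific", config$expr_effect, 0),
                 B = ifelse(linked_class == "B_specific", config$expr_effect, 0))
  expr <- tibble::tibble(gene_id = genes$gene_id)
  for (k in seq_along(sample_ids)) {
    x <- base + shift[, groups[k]] +
      stats::rnorm(nrow(genes), sd = config$expr_noise_sd)
    expr[[sample_ids[k]]] <- 2^x
  }

  make_cres <- function(group) {
    anchors <- anchor_intervals(paste0(group, "_specific"))
    n_signal <- round(config$cre_signal_frac * config$n_cres)
    cre_w <- 1e3
    out <- list()
    if (n_signal > 0 && nrow(anchors) > 0) {
      idx <- rep_len(seq_len(nrow(anchors)), n_signal)
      center <- (anchors$start[idx] + anchors$end[idx]) / 2
      out$signal <- tibble::tibble(chrom = config$chrom,
                                   start = pmax(0, center - cre_w / 2),
                                   end = pmin(config$chrom_length,
                                              center + cre_w / 2))
    }
    n_bg <- config$n_cres - n_signal
    if (n_bg > 0) {
      st <- round(stats::runif(n_bg, 0, config$chrom_length - cre_w))
      out$background <- tibble::tibble(chrom = config$chrom, start = st,
                                       end = st + cre_w)
    }
    dplyr::bind_rows(out)
  }
  cres <- list(A = make_cres("A"), B = make_cres("B"))

  phasing <- tibble::tibble(chrom = config$chrom,
                            start = truth$blocks$start,
                            end = truth$blocks$end,
                            value = truth$blocks$label_a +
                              stats::rnorm(nrow(truth$blocks), sd = 0.2))

  list(expr = expr,
       labels = tibble::tibble(sample = sample_ids, group = groups),
       genes = genes, cres = cres, phasing = phasing)
}
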