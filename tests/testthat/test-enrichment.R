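test_that("anchor-CRE overlap follows the either-anchor rule", {
  lp <- loops_from_bins(c(10, 40), c(60, 90))
  genome_wide <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(anchor_cre_overlap(lp, genome_wide), 1)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  expect_equal(anchor_cre_overlap(lp, empty), 0)

  only_a2 <- tibble::tibble(chrom = "chr1", start = 600500, end = 600900)
  expect_equal(anchor_cre_overlap(lp[1, ], only_a2), 1)
})

test_that("permutation p-values honour the add-one floor and degenerate CREs", {
  g <- toy_genome(1e6)
  lp <- loops_from_bins(c(10, 40), c(60, 90))
  tiling <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  res <- permutation_enrichment(lp, tiling, g, n_perm = 50, seed = 1)
  expect_equal(res$observed_fraction, 1)
  expect_true(all(res$null_fractions == 1))
  expect_equal(res$p_empirical, 1)

  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  res0 <- permutation_enrichment(lp, empty, g, n_perm = 50, seed = 1)
  expect_equal(res0$observed_fraction, 0)
  expect_equal(res0$p_empirical, 1)

  # determinism and the 1/(n+1) lower bound
  cres <- tibble::tibble(chrom = "chr1", start = c(1e5, 6e5),
                         end = c(1.01e5, 6.01e5))
  r1 <- permutation_enrichment(lp, cres, g, n_perm = 99, seed = 7)
  r2 <- permutation_enrichment(lp, cres, g, n_perm = 99, seed = 7)
  expect_identical(r1$null_fractions, r2$null_fractions)
  expect_gte(r1$p_empirical, 1 / 100)
})

test_that("CREs concentrated at loop anchors are declared enriched", {
  g <- toy_genome(1e7)
  lp <- loops_from_bins(seq(20, 920, by = 100), seq(60, 960, by = 100))
  at_anchors <- tibble::tibble(chrom = "chr1",
                               start = lp$start1 + 2000,
                               end = lp$start1 + 3000)
  res <- permutation_enrichment(lp, at_anchors, g, n_perm = 999, seed = 3)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$p_empirical, 1 / 1000)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("gene linking respects the +/- 3 kb flank arithmetic", {
  lp <- tibble::tibble(chrom1 = "chr1", start1 = 100000, end1 = 110000,
                       chrom2 = "chr1", start2 = 500000, end2 = 510000)
  genes <- tibble::tibble(
    gene_id = c("near", "far", "other_chrom"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(111000, 114000, 111000),
    end = c(115000, 118000, 115000),
    strand = "+")
  links <- link_genes(lp, genes, flank = 3000)
  expect_equal(links$gene_id, "near")

  # flank 0 equals plain intersection; linking is monotone in flank
  expect_equal(nrow(link_genes(lp, genes, flank = 0)), 0L)
  l1 <- link_genes(lp, genes, flank = 1000)
  l2 <- link_genes(lp, genes, flank = 10000)
  expect_true(all(l1$gene_id %in% l2$gene_id))
  expect_equal(sort(unique(l2$gene_id)), c("far", "near"))
})

test_that("differential expression matches hand-computed t and fold change", {
  expr <- tibble::tibble(gene_id = c("up", "flat", "small_fc"),
                         a1 = c(10, 5, 4.0), a2 = c(12, 5, 4.1),
                         a3 = c(11, 5, 4.0), a4 = c(11, 5, 4.1),
                         b1 = c(2, 5, 3.6), b2 = c(3, 5, 3.6),
                         b3 = c(2.5, 5, 3.6), b4 = c(2.5, 5, 3.7))
  labels <- tibble::tibble(sample = c(paste0("a", 1:4), paste0("b", 1:4)),
                           group = rep(c("A", "B"), each = 4))
  deg <- differential_expression(expr, labels)

  a <- c(10, 12, 11, 11); b <- c(2, 3, 2.5, 2.5)
  lfc_manual <- log2((mean(a) + 0.1) / (mean(b) + 0.1))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(deg$log2fc[1], lfc_manual)
  expect_equal(deg$p_value[1], tt$p.value)
  expect_gt(deg$log2fc[1], 2)
  expect_true(deg$significant[1])

  expect_equal(deg$log2fc[2], 0)
  expect_equal(deg$p_value[2], 1)
  expect_false(deg$significant[2])

  # tiny p but |log2FC| < 1: the fold-change floor rules it out
  expect_lt(deg$p_value[3], 0.05)
  expect_lt(abs(deg$log2fc[3]), 1)
  expect_false(deg$significant[3])

  expect_error(differential_expression(expr, labels[c(1, 2, 5), ]),
               "at least two")
})

test_that("TF-anchored filtering requires every peak set and honours exclusions", {
  lp <- loops_from_bins(c(10, 40, 70), c(60, 90, 120))
  peaks_at <- function(starts) {
    tibble::tibble(chrom = "chr1", start = starts * 1e4 + 100,
                   end = starts * 1e4 + 900)
  }
  tf1 <- peaks_at(c(10, 40, 70))       # at anchor1 of every loop
  tf2 <- peaks_at(c(10, 90))           # loop1 anchor1, loop2 anchor2
  kept <- annotate_tf_anchored(lp, list(tf1, tf2))
  expect_equal(kept$bin1, c(10L, 40L)) # loop3 lacks tf2 entirely

  kept_both <- annotate_tf_anchored(lp, list(tf1, tf2), both_anchors = TRUE)
  expect_equal(nrow(kept_both), 0L)

  excl <- loops_from_bins(10, 60)
  kept2 <- annotate_tf_anchored(lp, list(tf1, tf2), exclude_loops = excl)
  expect_equal(kept2$bin1, 40L)
})

test_that("cohort loops are enriched for own-group CREs but not the other group's", {
  run <- acceptance_run()
  expect_lte(run$enrichment$A$A$p_empirical, 0.01)
  expect_lte(run$enrichment$B$B$p_empirical, 0.01)
  expect_gt(run$enrichment$A$B$p_empirical, 0.1)
  expect_gt(run$enrichment$B$A$p_empirical, 0.1)
})

test_that("permutation calibration: uniform CREs are rejected at ~ alpha", {
  g <- toy_genome(2e7)
  cfg <- cohort_config(seed = 55, chrom_length = 2e7, n_shared = 20,
                       n_a_specific = 15, n_b_specific = 15)
  tr <- simulate_truth(cfg)
  lp <- tibble::tibble(chrom1 = tr$loops$chrom,
                       start1 = tr$loops$start1, end1 = tr$loops$end1,
                       chrom2 = tr$loops$chrom,
                       start2 = tr$loops$start2, end2 = tr$loops$end2)
  n_rep <- 100L
  reject <- logical(n_rep)
  withr::local_seed(808)
  for (r in seq_len(n_rep)) {
    st <- round(runif(120, 0, 2e7 - 1000))
    cres <- tibble::tibble(chrom = "chr1", start = st, end = st + 1000)
    cres$chrom <- tr$loops$chrom[1]
    res <- permutation_enrichment(lp, cres, genome_def(tr$loops$chrom[1], 2e7),
                                  n_perm = 200, seed = 9000 + r)
    reject[r] <- res$p_empirical <= 0.05
  }
  expect_gte(mean(reject), 0.01)
  expect_lte(mean(reject), 0.10)
})
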