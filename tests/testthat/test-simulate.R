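test_that("truth table respects configured loop counts and bounds", {
  cfg <- cohort_config(seed = 5, n_shared = 5, n_a_specific = 3,
                       n_b_specific = 2, chrom_length = 2e7)
  tr <- simulate_truth(cfg)
  expect_equal(as.vector(table(tr$loops$class)[c("shared", "A_specific",
                                                 "B_specific")]),
               c(5L, 3L, 2L))
  span <- (tr$loops$bin2 - tr$loops$bin1) * cfg$resolution
  expect_true(all(span >= cfg$min_span & span <= cfg$max_span))
  expect_true(all(tr$loops$bin2 < tr$n_bins))
  # pairwise collision guard
  n <- nrow(tr$loops)
  for (i in seq_len(n - 1)) {
    cheb <- pmax(abs(tr$loops$bin1[-(1:i)] - tr$loops$bin1[i]),
                 abs(tr$loops$bin2[-(1:i)] - tr$loops$bin2[i]))
    expect_gt(min(cheb), 10)
  }
})

test_that("simulation is deterministic and seed-sensitive", {
  cfg <- cohort_config(seed = 9, chrom_length = 3e6, depth = 2e5,
                       n_shared = 2, n_a_specific = 1, n_b_specific = 1,
                       min_span = 1e5, max_span = 5e5)
  tr <- simulate_truth(cfg)
  m1 <- simulate_contact_map(cfg, tr, "A", 123)
  m2 <- simulate_contact_map(cfg, tr, "A", 123)
  expect_identical(m1$pixels, m2$pixels)
  m3 <- simulate_contact_map(cfg, tr, "A", 124)
  expect_false(identical(m1$pixels, m3$pixels))
})

test_that("zero depth yields an empty map", {
  cfg <- cohort_config(seed = 2, chrom_length = 2e6, depth = 0,
                       n_shared = 0, n_a_specific = 0, n_b_specific = 0)
  tr <- simulate_truth(cfg)
  m <- simulate_contact_map(cfg, tr, "A", 1)
  expect_equal(nrow(m$pixels), 0L)
})

test_that("planted loop pixels are enriched about phi-fold over background", {
  cfg <- cohort_config(seed = 31, chrom_length = 1e7, depth = 1e7,
                       loop_enrichment = 8, compartment_strength = 1,
                       n_shared = 0, n_a_specific = 8, n_b_specific = 0,
                       min_span = 2e5, max_span = 8e5)
  tr <- simulate_truth(cfg)
  m <- simulate_contact_map(cfg, tr, "A", 77)
  px <- m$pixels
  key <- paste(px$bin1, px$bin2)
  lp <- tr$loops
  obs <- px$count[match(paste(lp$bin1, lp$bin2), key)]
  obs[is.na(obs)] <- 0
  # matched-distance background mean: all pixels at the same bin distance
  d_all <- px$bin2 - px$bin1
  bg <- vapply(lp$bin2 - lp$bin1, function(d) {
    sum(px$count[d_all == d]) / (tr$n_bins - d)
  }, 0)
  ratio <- mean(obs) / mean(bg)
  expect_gt(ratio, cfg$loop_enrichment * 0.9)
  expect_lt(ratio, cfg$loop_enrichment * 1.1)
})

test_that("group-specific loops are stronger in their own group's maps", {
  cfg <- small_cohort_config(seed = 12)
  co <- simulate_cohort(cfg)
  lp <- co$truth$loops[co$truth$loops$class == "A_specific", ]
  count_at <- function(map, b1, b2) {
    px <- map$pixels
    v <- px$count[px$bin1 == b1 & px$bin2 == b2]
    if (length(v)) v else 0
  }
  for (k in seq_len(nrow(lp))) {
    in_a <- mean(vapply(co$maps[co$labels$group == "A"], count_at, 0,
                        lp$bin1[k], lp$bin2[k]))
    in_b <- mean(vapply(co$maps[co$labels$group == "B"], count_at, 0,
                        lp$bin1[k], lp$bin2[k]))
    expect_gt(in_a, in_b)
  }
})

test_that("distance decay is monotone decreasing (Spearman)", {
  cfg <- cohort_config(seed = 8, chrom_length = 5e6, depth = 2e6,
                       n_shared = 0, n_a_specific = 0, n_b_specific = 0)
  tr <- simulate_truth(cfg)
  m <- simulate_contact_map(cfg, tr, "A", 3)
  px <- m$pixels
  d <- px$bin2 - px$bin1
  n <- tr$n_bins
  dmax <- n - 1L
  sums <- tapply(px$count, factor(d, levels = 0:dmax), sum, default = 0)
  mean_by_d <- as.numeric(sums) / (n - 0:dmax)
  ct <- suppressWarnings(
    cor.test(0:dmax, mean_by_d, method = "spearman", alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("expression effect and CRE placement follow the configuration", {
  cfg <- small_cohort_config(seed = 21)
  tr <- simulate_truth(cfg)
  aux <- simulate_expression_and_cres(cfg, tr)
  linked <- aux$genes$linked_class == "A_specific"
  skip_if(sum(linked) < 2)
  lx <- log2(as.matrix(aux$expr[, aux$labels$sample]))
  grp <- aux$labels$group
  lfc <- rowMeans(lx[, grp == "A"]) - rowMeans(lx[, grp == "B"])
  se <- cfg$expr_noise_sd * sqrt(1 / sum(grp == "A") + 1 / sum(grp == "B")) /
    sqrt(sum(linked))
  expect_lt(abs(mean(lfc[linked]) - cfg$expr_effect), 3 * se)
  expect_lt(abs(mean(lfc[aux$genes$linked_class == "none"])), 0.2)

  cfg2 <- cohort_config(seed = 3, chrom_length = 8e6, cre_signal_frac = 1,
                        n_shared = 0, n_a_specific = 5, n_b_specific = 5,
                        n_cres = 40)
  tr2 <- simulate_truth(cfg2)
  aux2 <- simulate_expression_and_cres(cfg2, tr2)
  anchors <- tr2$loops[tr2$loops$class == "A_specific", ]
  anchor_iv <- tibble::tibble(
    chrom = rep(anchors$chrom, 2L),
    start = c(anchors$start1, anchors$start2),
    end = c(anchors$end1, anchors$end2))
  hit <- loopdiffr:::overlaps_any_intervals(aux2$cres$A, anchor_iv)
  expect_true(all(hit))
})

test_that("expr_effect = 0 leaves linked and unlinked group means equal", {
  cfg <- cohort_config(seed = 6, chrom_length = 8e6, expr_effect = 0,
                       n_shared = 0, n_a_specific = 6, n_b_specific = 6,
                       n_genes = 200)
  tr <- simulate_truth(cfg)
  aux <- simulate_expression_and_cres(cfg, tr)
  lx <- log2(as.matrix(aux$expr[, aux$labels$sample]))
  grp <- aux$labels$group
  lfc <- rowMeans(lx[, grp == "A"]) - rowMeans(lx[, grp == "B"])
  linked <- aux$genes$linked_class != "none"
  skip_if(sum(linked) < 2)
  expect_lt(abs(mean(lfc[linked]) - mean(lfc[!linked])), 0.5)
})
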