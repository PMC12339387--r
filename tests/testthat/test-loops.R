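# A deterministic decay map whose counts equal the loop-free model has no
# pixel above its own local background, so the caller must stay silent; a
# single strongly enriched pixel must be found exactly once.

test_that("a loop-free deterministic decay map yields zero loops", {
  m <- decay_map(n_bins = 150, scale = 600, balanced = TRUE)
  ex <- compute_expected(m)
  calls <- call_loops(m, ex, min_dist = 6e4, max_dist = 1e6)
  expect_equal(nrow(calls), 0L)
})

test_that("a single planted pixel at 20x background is called exactly once", {
  n <- 150L
  g <- toy_genome(n * 1e4)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  count <- round(600 / (d + 1))
  hit <- idx[, 1] == 41L & idx[, 2] == 101L   # bins (40, 100), d = 60
  count[hit] <- 20 * count[hit]
  m <- contact_map(tibble::tibble(chrom = "chr1", bin1 = idx[, 1] - 1L,
                                  bin2 = idx[, 2] - 1L, count = count),
                   g, 1e4, balanced = TRUE)
  ex <- compute_expected(m)
  calls <- call_loops(m, ex, min_dist = 6e4, max_dist = 1.2e6)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$bin1, 40L)
  expect_equal(calls$bin2, 100L)
  expect_lt(calls$q_value, 1e-6)
  # closed-form Poisson check of the same pixel (known-background mode)
  calls_pois <- call_loops(m, ex, min_dist = 6e4, max_dist = 1.2e6,
                           background_uncertainty = FALSE)
  sf <- loopdiffr:::surface_for_map(m, ex, 1.2e6)$chr1
  p_direct <- ppois(ceiling(sf$raw_obs[41, 61]) - 1,
                    sf$lambda_raw[41, 61], lower.tail = FALSE)
  expect_equal(calls_pois$p_value[1], p_direct)
})

test_that("pixels below the minimum distance are never called", {
  n <- 100L
  g <- toy_genome(n * 1e4)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  count <- round(400 / (d + 1))
  count[idx[, 1] == 21L & idx[, 2] == 24L] <- 500   # d = 3 < min_dist
  m <- contact_map(tibble::tibble(chrom = "chr1", bin1 = idx[, 1] - 1L,
                                  bin2 = idx[, 2] - 1L, count = count),
                   g, 1e4, balanced = TRUE)
  ex <- compute_expected(m)
  calls <- call_loops(m, ex, min_dist = 6e4, max_dist = 8e5)
  expect_false(any(calls$bin1 == 20L & calls$bin2 == 23L))
})

test_that("calls are invariant to pixel storage order", {
  n <- 150L
  g <- toy_genome(n * 1e4)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  count <- round(600 / (d + 1))
  count[idx[, 1] == 31L & idx[, 2] == 81L] <- 10 * count[idx[, 1] == 31L &
                                                           idx[, 2] == 81L]
  px <- tibble::tibble(chrom = "chr1", bin1 = idx[, 1] - 1L,
                       bin2 = idx[, 2] - 1L, count = count)
  m1 <- contact_map(px, g, 1e4, balanced = TRUE)
  m2 <- contact_map(px[sample.int(nrow(px)), ], g, 1e4, balanced = TRUE)
  c1 <- call_loops(m1, compute_expected(m1), min_dist = 6e4, max_dist = 1e6)
  c2 <- call_loops(m2, compute_expected(m2), min_dist = 6e4, max_dist = 1e6)
  expect_equal(c1, c2)
})

test_that("pixel_stats matches the uniform-map identity and flags masked bins", {
  m <- uniform_map(n_bins = 40, value = 2)
  ex <- compute_expected(m)
  st <- pixel_stats(m, ex, tibble::tibble(chrom = "chr1", bin1 = 5L,
                                          bin2 = 25L))
  expect_true(st$defined)
  expect_equal(st$oe, 1)
  expect_equal(st$local_background, 2)   # = expected when O/E is flat

  m$mask$chr1[11] <- FALSE
  st2 <- pixel_stats(m, ex, tibble::tibble(chrom = "chr1", bin1 = 10L,
                                           bin2 = 25L))
  expect_false(st2$defined)
  expect_true(is.na(st2$oe))
})

test_that("planted enrichment is recovered by pixel_stats within 15%", {
  cfg <- cohort_config(seed = 19, chrom_length = 1e7, depth = 1e7,
                       loop_enrichment = 10, compartment_strength = 1,
                       n_shared = 0, n_a_specific = 6, n_b_specific = 0,
                       min_span = 2e5, max_span = 8e5)
  tr <- simulate_truth(cfg)
  m <- simulate_contact_map(cfg, tr, "A", 7)
  bal <- ice_balance(m)
  ex <- compute_expected(bal)
  lp <- tr$loops
  st <- pixel_stats(bal, ex, tibble::tibble(chrom = lp$chrom,
                                            bin1 = lp$bin1, bin2 = lp$bin2))
  expect_true(all(st$defined))
  expect_lt(abs(mean(st$oe) - 10) / 10, 0.15)
})

test_that("loop-free simulated maps rarely produce any call", {
  n_rep <- 200L
  any_call <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(seed = 3000 + r, chrom_length = 3e6, depth = 6e5,
                         n_shared = 0, n_a_specific = 0, n_b_specific = 0,
                         n_group_a = 1, n_group_b = 0)
    tr <- simulate_truth(cfg)
    m <- simulate_contact_map(cfg, tr, "A", 40000 + r)
    bal <- ice_balance(m)
    any_call[r] <- nrow(call_loops(bal, compute_expected(bal))) > 0
  }
  expect_lte(mean(any_call), 0.10)
})

test_that("planted loops at phi >= 6 and deep coverage are recalled at >= 90%", {
  cfg <- cohort_config(seed = 23, chrom_length = 1e7, depth = 1e7,
                       loop_enrichment = 6,
                       n_shared = 0, n_a_specific = 15, n_b_specific = 0,
                       min_span = 2e5, max_span = 1e6)
  tr <- simulate_truth(cfg)
  m <- simulate_contact_map(cfg, tr, "A", 31)
  bal <- ice_balance(m)
  calls <- call_loops(bal, compute_expected(bal))
  calls_sig <- calls[calls$q_value <= 0.05, ]
  hit <- paste(tr$loops$bin1, tr$loops$bin2) %in%
    paste(calls_sig$bin1, calls_sig$bin2)
  expect_gte(mean(hit), 0.9)
})
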