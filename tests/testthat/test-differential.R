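# Noise-free pair of decay maps with a loop planted in x only: the
# conditional binomial tail can be computed directly and compared.

make_pair <- function(phi_x = 10, phi_y = 1, n = 150L, scale = 600) {
  g <- toy_genome(n * 1e4)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  base <- round(scale / (d + 1))
  hit <- idx[, 1] == 41L & idx[, 2] == 101L
  cx <- base; cx[hit] <- round(phi_x * base[hit])
  cy <- base; cy[hit] <- round(phi_y * base[hit])
  mk <- function(cnt) contact_map(
    tibble::tibble(chrom = "chr1", bin1 = idx[, 1] - 1L,
                   bin2 = idx[, 2] - 1L, count = cnt),
    g, 1e4, balanced = TRUE)
  list(x = mk(cx), y = mk(cy))
}

test_that("identical maps produce no differential loops", {
  pr <- make_pair(phi_x = 10, phi_y = 10)
  ex <- compute_expected(pr$x)
  loops_x <- call_loops(pr$x, ex, min_dist = 6e4, max_dist = 1.2e6)
  expect_equal(nrow(loops_x), 1L)
  diff <- pairwise_differential(loops_x, pr$x, pr$y, ex, ex)
  expect_equal(nrow(diff), 0L)
})

test_that("a loop present only in x is differential, with the exact binomial tail", {
  pr <- make_pair(phi_x = 10, phi_y = 1)
  ex_x <- compute_expected(pr$x)
  ex_y <- compute_expected(pr$y)
  loops_x <- call_loops(pr$x, ex_x, min_dist = 6e4, max_dist = 1.2e6)
  diff <- pairwise_differential(loops_x, pr$x, pr$y, ex_x, ex_y)
  expect_equal(nrow(diff), 1L)
  expect_equal(diff$bin1, 40L)
  expect_lt(diff$diff_q, 1e-3)

  # independent tail: obs_x vs obs_y with background-proportional exposure
  sfx <- loopdiffr:::surface_for_map(pr$x, ex_x, 1.2e6)$chr1
  sfy <- loopdiffr:::surface_for_map(pr$y, ex_y, 1.2e6)$chr1
  ox <- round(sfx$raw_obs[41, 61]); lx <- sfx$lambda_raw[41, 61]
  # y's matched pixel is its 3x3 O/E maximum around (40, 100)
  cand <- expand.grid(di = -1:1, dj = -1:1)
  oes <- mapply(function(a, b) sfy$OE[41 + a, 61 + b - a], cand$di, cand$dj)
  k <- which.max(oes)
  oy <- round(sfy$raw_obs[41 + cand$di[k], 61 + cand$dj[k] - cand$di[k]])
  ly <- sfy$lambda_raw[41 + cand$di[k], 61 + cand$dj[k] - cand$di[k]]
  p_direct <- pbinom(ox - 1, ox + oy, lx / (lx + ly), lower.tail = FALSE)
  expect_equal(diff$diff_p, p_direct)
})

test_that("resolution mismatch is rejected", {
  pr <- make_pair()
  y2 <- pr$y; y2$resolution <- 5000L
  expect_error(pairwise_differential(empty_loops <- loops_from_bins(1, 50),
                                     pr$x, y2, NULL, NULL),
               "resolution mismatch")
})

test_that("match_loops applies the per-anchor tolerance and greedy pairing", {
  a <- loops_from_bins(c(10, 40), c(60, 90))
  expect_equal(nrow(match_loops(a, a, tol_bins = 1)), 2L)

  b <- loops_from_bins(c(11, 42), c(61, 91))  # +1/+1 and +2/+1 offsets
  mm <- match_loops(a, b, tol_bins = 1)
  expect_equal(mm$idx_a, 1L)                  # loop 2 offset exceeds tol

  b2 <- loops_from_bins(12, 60)               # anchor1 off by 2
  expect_equal(nrow(match_loops(a, b2, tol_bins = 1)), 0L)

  # each loop used at most once
  many <- loops_from_bins(c(10, 10), c(60, 61))
  mm2 <- match_loops(many, a[1, ], tol_bins = 1)
  expect_equal(nrow(mm2), 1L)
})

test_that("gained loops require the pairwise support threshold", {
  lp <- loops_from_bins(c(10, 40), c(60, 90))
  pw <- list(c1 = lp[1, ], c2 = lp, c3 = lp[2, ], c4 = lp[2, ])
  gained <- gained_loops_for_sample(pw, min_pairwise = 2)
  expect_equal(gained$bin1, c(10L, 40L))
  expect_equal(gained$n_pairwise, c(2L, 3L))
  gained3 <- gained_loops_for_sample(pw, min_pairwise = 3)
  expect_equal(gained3$bin1, 40L)

  # coordinates 2 bins apart are distinct identities at tol 1
  pw2 <- list(c1 = loops_from_bins(10, 60), c2 = loops_from_bins(12, 60))
  expect_equal(nrow(gained_loops_for_sample(pw2, min_pairwise = 2)), 0L)
})

test_that("subtype consensus equals brute-force evaluation on indicator instances", {
  # indicator[l, s, c]: loop l differential in comparison c of sample s
  brute <- function(ind, min_pairwise = 2, min_samples = 2) {
    per_sample <- apply(ind, c(1, 2), sum) >= min_pairwise
    which(rowSums(per_sample) >= min_samples)
  }
  run_package <- function(ind, min_pairwise = 2, min_samples = 2) {
    n_loop <- dim(ind)[1]
    coords <- loops_from_bins(seq(10, by = 20, length.out = n_loop),
                              seq(210, by = 20, length.out = n_loop))
    gained <- lapply(seq_len(dim(ind)[2]), function(s) {
      pw <- lapply(seq_len(dim(ind)[3]), function(cc) {
        coords[ind[, s, cc], , drop = FALSE]
      })
      names(pw) <- sprintf("cmp%d", seq_along(pw))
      gained_loops_for_sample(pw, min_pairwise = min_pairwise)
    })
    names(gained) <- sprintf("S%d", seq_along(gained))
    rep <- subtype_enriched_loops(gained, min_samples = min_samples)
    sort(match(rep$loops$bin1, coords$bin1))
  }
  set.seed(421)
  for (rep_i in 1:20) {
    ind <- array(runif(10 * 4 * 4) < 0.45, dim = c(10, 4, 4))
    expect_equal(run_package(ind), unname(brute(ind)))
  }
  # dense and empty corners
  expect_equal(run_package(array(TRUE, c(3, 4, 4))), 1:3)
  expect_equal(length(run_package(array(FALSE, c(3, 4, 4)))), 0L)
})

test_that("consensus is symmetric under group relabeling and monotone in thresholds", {
  set.seed(77)
  ind <- array(runif(8 * 4 * 4) < 0.5, dim = c(8, 4, 4))
  coords <- loops_from_bins(seq(10, by = 20, length.out = 8),
                            seq(210, by = 20, length.out = 8))
  gained_from <- function(ind, min_pairwise = 2) {
    out <- lapply(1:4, function(s) {
      pw <- lapply(1:4, function(cc) coords[ind[, s, cc], , drop = FALSE])
      names(pw) <- sprintf("cmp%d", 1:4)
      gained_loops_for_sample(pw, min_pairwise = min_pairwise)
    })
    names(out) <- sprintf("S%d", 1:4)
    out
  }
  r1 <- subtype_enriched_loops(gained_from(ind), group = "A")
  r2 <- subtype_enriched_loops(gained_from(ind), group = "B")
  expect_equal(r1$loops[names(r1$loops) != "samples"],
               r2$loops[names(r2$loops) != "samples"])

  loose <- subtype_enriched_loops(gained_from(ind, min_pairwise = 1),
                                  min_samples = 2)
  tight <- subtype_enriched_loops(gained_from(ind, min_pairwise = 3),
                                  min_samples = 3)
  expect_true(all(tight$loops$bin1 %in% loose$loops$bin1))

  expect_error(subtype_enriched_loops(gained_from(ind)[1], min_samples = 2),
               "fewer samples")
})
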