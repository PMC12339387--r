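# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

toy_genome <- function(len = 1e6, chrom = "chr1") genome_def(chrom, len)

# Map with every upper-triangle pixel present at a constant value: O/E is
# exactly 1 everywhere once flagged balanced.
uniform_map <- function(n_bins = 40L, value = 2, resolution = 1e4,
                        chrom = "chr1") {
  g <- genome_def(chrom, n_bins * resolution)
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
               arr.ind = TRUE)
  contact_map(tibble::tibble(chrom = chrom, bin1 = idx[, 1] - 1L,
                             bin2 = idx[, 2] - 1L, count = value),
              g, resolution, balanced = TRUE)
}

# Deterministic loop-free decay map: counts = round(scale / (d + 1)).
decay_map <- function(n_bins = 120L, scale = 120, resolution = 1e4,
                      chrom = "chr1", balanced = FALSE) {
  g <- genome_def(chrom, n_bins * resolution)
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
               arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  contact_map(tibble::tibble(chrom = chrom, bin1 = idx[, 1] - 1L,
                             bin2 = idx[, 2] - 1L,
                             count = round(scale / (d + 1))),
              g, resolution, balanced = balanced)
}

# Loop tibble from bare bin pairs.
loops_from_bins <- function(bin1, bin2, resolution = 1e4, chrom = "chr1") {
  tibble::tibble(chrom1 = chrom, start1 = bin1 * resolution,
                 end1 = (bin1 + 1) * resolution,
                 chrom2 = chrom, start2 = bin2 * resolution,
                 end2 = (bin2 + 1) * resolution,
                 bin1 = as.integer(bin1), bin2 = as.integer(bin2))
}

# Small quick cohort for pipeline-level tests.
small_cohort_config <- function(seed = 42L) {
  cohort_config(seed = seed, chrom_length = 8e6, depth = 3e6,
                n_shared = 5, n_a_specific = 4, n_b_specific = 4,
                min_span = 1.5e5, max_span = 8e5,
                n_cres = 80, n_genes = 150)
}

# Raw contact map from a dense symmetric matrix.
map_from_dense <- function(A, resolution = 1e4, chrom = "chr1") {
  idx <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  contact_map(tibble::tibble(chrom = chrom, bin1 = idx[, 1] - 1L,
                             bin2 = idx[, 2] - 1L, count = A[idx]),
              genome_def(chrom, nrow(A) * resolution), resolution)
}

# Independent dense fixed-point oracle for ICE balancing, iterated to
# machine-level convergence on the full symmetric matrix.
ice_oracle <- function(A, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(A)
  b <- rep(1, n)
  mappable <- rowSums(A) > 0
  for (it in seq_len(max_iter)) {
    W <- A / outer(b, b)
    m <- rowSums(W)
    s <- m[mappable]
    if (max(abs(s / mean(s) - 1)) < tol) break
    b[mappable] <- b[mappable] * s / mean(s)
  }
  b <- b / mean(b[mappable])
  b[!mappable] <- NA
  b
}

# Deterministic two-block checkerboard at compartment resolution: same-label
# bin pairs enriched by `strength`, opposite-label depleted.
checkerboard_map <- function(n = 60L, block = 10L, strength = 2,
                             resolution = 1e5, noise_sd = 0) {
  g <- genome_def("chr1", n * resolution)
  lab <- rep(rep(c(1L, -1L), length.out = n %/% block), each = block)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  fac <- ifelse(lab[idx[, 1]] == lab[idx[, 2]], strength, 1 / strength)
  cnt <- 50 / (d + 1) * fac
  if (noise_sd > 0) cnt <- cnt * exp(rnorm(length(cnt), sd = noise_sd))
  m <- contact_map(tibble::tibble(chrom = "chr1", bin1 = idx[, 1] - 1L,
                                  bin2 = idx[, 2] - 1L, count = cnt),
                   g, resolution, balanced = TRUE)
  list(map = m, labels = lab)
}

block_phasing <- function(labels, resolution = 1e5) {
  n <- length(labels)
  tibble::tibble(chrom = "chr1", start = (0:(n - 1)) * resolution,
                 end = (1:n) * resolution, value = as.numeric(labels))
}
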