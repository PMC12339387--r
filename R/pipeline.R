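#' Analysis configuration
#'
#' Bundles every threshold of the differential-architecture pipeline; the
#' defaults are the standard operating point of the method (loop-call FDR
#' 0.05, differential FDR 0.001, two supporting pairwise comparisons in
#' two or more samples, 5-bin APA window, +/-3 kb gene flank, 1,000
#' permutations, DE at p < 0.05 and |log2FC| >= 1, top 25% variable
#' compartment bins, 1-bin matching tolerance).
#'
#' @param resolution Loop-calling bin size in bp (default 10,000).
#' @param compartment_resolution Compartment bin size in bp (100,000).
#' @param fdr_call,fdr_diff Loop-call and differential BH thresholds.
#' @param min_pairwise,min_samples Consensus support thresholds.
#' @param apa_window_bins APA window in bins (default 5).
#' @param gene_flank Gene-linking flank in bp (default 3,000).
#' @param n_perm CRE permutation count (default 1,000).
#' @param de_p,de_lfc DE significance thresholds (0.05, 1).
#' @param top_variable_frac Compartment variable-bin fraction (0.25).
#' @param tol_bins Loop matching tolerance in bins (default 1).
#' @param min_dist,max_dist Loop-call distance range in bp (50 kb, 2 Mb).
#' @param seed Root seed for the pipeline's own randomness.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(resolution = 1e4, compartment_resolution = 1e5,
                            fdr_call = 0.05, fdr_diff = 0.001,
                            min_pairwise = 2L, min_samples = 2L,
                            apa_window_bins = 5L, gene_flank = 3e3,
                            n_perm = 1000L, de_p = 0.05, de_lfc = 1,
                            top_variable_frac = 0.25, tol_bins = 1L,
                            min_dist = 5e4, max_dist = 2e6, seed = 1L) {
  cfg <- list(resolution = resolution,
              compartment_resolution = compartment_resolution,
              fdr_call = fdr_call, fdr_diff = fdr_diff,
              min_pairwise = as.integer(min_pairwise),
              min_samples = as.integer(min_samples),
              apa_window_bins = as.integer(apa_window_bins),
              gene_flank = gene_flank, n_perm = as.integer(n_perm),
              de_p = de_p, de_lfc = de_lfc,
              top_variable_frac = top_variable_frac,
              tol_bins = as.integer(tol_bins),
              min_dist = min_dist, max_dist = max_dist,
              seed = as.integer(seed))
  stopifnot(cfg$fdr_call > 0, cfg$fdr_diff > 0, cfg$min_pairwise >= 1,
            cfg$min_samples >= 1, cfg$apa_window_bins %% 2L == 1L,
            cfg$n_perm >= 1, cfg$top_variable_frac > 0,
            cfg$top_variable_frac <= 1)
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full differential-architecture pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> balance -> expected -> loop calling ->
#' pairwise differential -> two-level consensus -> APA group contrast ->
#' compartment eigenvector clustering -> CRE permutation enrichment ->
#' gene linking with differential expression, and evaluates every stage
#' against the planted truth. Deterministic given the two configs.
#'
#' @param config An [analysis_config()].
#' @param sim_config A [cohort_config()]; the synthetic cohort to analyse.
#' @param out_dir Optional directory; per-stage text outputs (BEDPE, TSV)
#'   are written there.
#' @param quiet Suppress progress messages (default TRUE).
#' @return A `loopdiff_run` list; see `glance()` for the one-row summary.
#' @export
run_full <- function(config = analysis_config(),
                     sim_config = cohort_config(),
                     out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  n_a <- sim_config$n_group_a; n_b <- sim_config$n_group_b
  if (min(n_a, n_b) < config$min_samples) {
    stop("min_samples (", config$min_samples,
         ") exceeds the smaller group size (", min(n_a, n_b), ")")
  }
  say("simulating cohort")
  cohort <- simulate_cohort(sim_config)
  aux <- simulate_expression_and_cres(sim_config, cohort$truth)
  samples <- cohort$labels$sample
  groups <- stats::setNames(cohort$labels$group, samples)

  say("balancing and calling loops")
  bal <- list(); expd <- list(); loops <- list(); surf <- list()
  for (s in samples) {
    bal[[s]] <- ice_balance(cohort$maps[[s]])
    expd[[s]] <- compute_expected(bal[[s]])
    surf[[s]] <- surface_for_map(bal[[s]], expd[[s]], config$max_dist)
    loops[[s]] <- call_loops(bal[[s]], expd[[s]], fdr = config$fdr_call,
                             min_dist = config$min_dist,
                             max_dist = config$max_dist, sample_id = s)
    say("  ", s, ": ", nrow(loops[[s]]), " loops")
  }

  say("pairwise differential and consensus")
  consensus <- list()
  for (g in c("A", "B")) {
    own <- samples[groups == g]
    opp <- samples[groups != g]
    gained <- purrr::map(own, function(x) {
      pw <- purrr::map(opp, function(y) {
        pairwise_differential(loops[[x]], bal[[x]], bal[[y]],
                              expd[[x]], expd[[y]],
                              fdr_diff = config$fdr_diff,
                              fdr_call = config$fdr_call,
                              surface_x = surf[[x]], surface_y = surf[[y]])
      })
      names(pw) <- paste(x, "vs", opp)
      gained_loops_for_sample(pw, min_pairwise = config$min_pairwise,
                              tol_bins = config$tol_bins)
    })
    names(gained) <- own
    consensus[[g]] <- subtype_enriched_loops(gained, group = g,
                                             min_samples = config$min_samples,
                                             tol_bins = config$tol_bins,
                                             resolution = config$resolution)
    say("  group ", g, ": ", nrow(consensus[[g]]$loops), " enriched loops")
  }

  say("APA group contrast")
  apa <- list()
  for (g in c("A", "B")) {
    lp <- consensus[[g]]$loops
    if (nrow(lp) == 0L) {
      apa[[g]] <- NULL
      next
    }
    scores <- vapply(samples, function(s) {
      pileup(bal[[s]], expd[[s]], lp,
             window_bins = config$apa_window_bins)$apa_score
    }, 0)
    own_scores <- scores[groups == g]
    opp_scores <- scores[groups != g]
    apa[[g]] <- list(scores = scores,
                     test = compare_apa_groups(own_scores, opp_scores,
                                               alternative = "greater"))
  }

  say("compartment eigenvectors")
  factor <- as.integer(config$compartment_resolution %/% config$resolution)
  tracks <- purrr::map(samples, function(s) {
    cmap <- ice_balance(coarsen_map(cohort$maps[[s]], factor))
    compartment_eigenvector(cmap, compute_expected(cmap), aux$phasing,
                            sample_id = s)
  })
  names(tracks) <- samples
  comp_corr <- variable_bin_correlation(tracks,
                                        top_frac = config$top_variable_frac)
  comp_clusters <- cluster_samples(comp_corr, k = 2L)

  say("CRE enrichment")
  genome <- sim_genome(sim_config)
  enrichment <- list()
  for (g in c("A", "B")) {
    lp <- consensus[[g]]$loops
    enrichment[[g]] <- purrr::map(c(A = "A", B = "B"), function(cre_g) {
      permutation_enrichment(lp, aux$cres[[cre_g]], genome,
                             n_perm = config$n_perm,
                             seed = config$seed + match(g, c("A", "B")) * 1000L +
                               match(cre_g, c("A", "B")))
    })
  }

  say("gene linking and differential expression")
  deg <- differential_expression(aux$expr, aux$labels,
                                 p_thresh = config$de_p,
                                 lfc_thresh = config$de_lfc)
  links <- purrr::map(c(A = "A", B = "B"), function(g) {
    link_genes(consensus[[g]]$loops, aux$genes, flank = config$gene_flank)
  })

  truth_eval <- evaluate_against_truth(consensus, cohort$truth,
                                       tol_bins = config$tol_bins)

  run <- structure(list(config = config, sim_config = sim_config,
                        truth = cohort$truth, labels = cohort$labels,
                        loops = loops, consensus = consensus, apa = apa,
                        comp_corr = comp_corr, comp_clusters = comp_clusters,
                        tracks = tracks, enrichment = enrichment, deg = deg,
                        links = links, genes = aux$genes, expr = aux$expr,
                        cres = aux$cres, truth_eval = truth_eval),
                   class = "loopdiff_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# Compare consensus reports to the planted truth: recovery of each
# group-specific class in its own group's report, and leakage of shared
# loops into either report.
evaluate_against_truth <- function(consensus, truth, tol_bins = 1L) {
  truth_tbl <- function(class) {
    lp <- truth$loops[truth$loops$class == class, ]
    tibble::tibble(chrom1 = lp$chrom, bin1 = lp$bin1, bin2 = lp$bin2)
  }
  rec <- function(class, group) {
    tt <- truth_tbl(class)
    if (nrow(tt) == 0L) return(NA_real_)
    nrow(match_loops(tt, consensus[[group]]$loops, tol_bins = tol_bins)) /
      nrow(tt)
  }
  shared <- truth_tbl("shared")
  shared_reported <- sum(vapply(c("A", "B"), function(g) {
    nrow(match_loops(shared, consensus[[g]]$loops, tol_bins = tol_bins))
  }, 0L))
  tibble::tibble(recovery_a = rec("A_specific", "A"),
                 recovery_b = rec("B_specific", "B"),
                 shared_reported = shared_reported,
                 n_enriched_a = nrow(consensus[["A"]]$loops),
                 n_enriched_b = nrow(consensus[["B"]]$loops))
}

#' @export
print.loopdiff_run <- function(x, ...) {
  cat("<loopdiff_run>\n")
  print(glance(x))
  invisible(x)
}

#' @export
glance.loopdiff_run <- function(x, ...) {
  dplyr::bind_cols(
    x$truth_eval,
    tibble::tibble(
      apa_p_a = if (!is.null(x$apa$A)) x$apa$A$test$p_value else NA_real_,
      apa_p_b = if (!is.null(x$apa$B)) x$apa$B$test$p_value else NA_real_,
      cre_p_a_own = x$enrichment$A$A$p_empirical,
      cre_p_b_own = x$enrichment$B$B$p_empirical,
      n_deg = sum(x$deg$significant)))
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in c("A", "B")) {
    lp <- run$consensus[[g]]$loops
    if (nrow(lp)) {
      write_bedpe(lp, file.path(out_dir,
                                sprintf("enriched_loops_%s.bedpe", g)))
    }
    readr::write_tsv(lp, file.path(out_dir,
                                   sprintf("enriched_loops_%s.tsv", g)))
  }
  readr::write_tsv(run$deg, file.path(out_dir, "differential_expression.tsv"))
  readr::write_tsv(run$truth_eval, file.path(out_dir, "truth_eval.tsv"))
  utils::write.table(run$comp_corr,
                     file.path(out_dir, "compartment_correlation.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(out_dir)
}
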