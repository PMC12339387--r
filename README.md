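# loopdiffr

Differential three-dimensional chromatin architecture analysis for
two-group Hi-C cohorts — for computational biologists comparing, say, two
tumour subtypes, treatment arms, or cell states profiled by Hi-C, who want
to know **which chromatin loops distinguish the groups** and what those
loops touch.

From balanced cis contact maps the package takes you to:

* **Subtype-enriched loop sets** via a two-level consensus: per-sample loop
  calls (local-background test, BH FDR 0.05), exact conditional-binomial
  rate tests between every cross-group sample pair (FDR 0.001, O/E ratio
  ≥ 1.5), loops *gained* for a sample when differential in ≥ 2 of its
  pairwise comparisons, and *subtype-enriched* when gained in ≥ 2 samples
  of a group.
* **Aggregate peak analysis (APA)**: mean O/E in a 50 kb × 50 kb window
  centred on loop pixels; the APA score is the mean of the central 3 × 3;
  group contrasts by one-sided Student's t test on per-sample scores.
* **A/B compartment tracks**: leading eigenvector of the O/E correlation
  matrix at 100 kb, phasing-oriented; samples clustered on Pearson
  correlations over the top 25% most variable bins.
* **CRE enrichment**: fraction of loops with either anchor in a
  regulatory-element set, tested against 1,000 chromosome-matched
  permutations of equal-width random anchors
  (add-one empirical p, floor 1/1001).
* **Gene integration**: genes within ±3 kb of loop anchors, joined to
  per-gene t tests on FPKM (significant at p < 0.05, |log2FC| ≥ 1).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods. A synthetic cohort
generator (`cohort_config()`, `simulate_cohort()`) plants shared and
group-specific loops of known strength in power-law Poisson contact maps
with compartment structure, matched CRE sets and expression effects, so
the whole pipeline is validated end to end against a known truth — no
external data needed.

## Core model in brief

Counts at bin pair $(i,j)$ are modelled around
$\lambda_{ij} = e(d)\, b_i b_j \cdot \text{local enrichment}$, where
$e(d)$ is the mean balanced contact at bin distance $d = |i-j|$ and $b$
are ICE biases. A loop is a pixel whose raw-equivalent count exceeds a
local background $e(d) \cdot \max_k \widehat{OE}_k$ taken over donut,
quadrant and one-sided stripe neighborhoods, tested with a gamma–Poisson
tail that propagates the background estimator's own sampling noise.
Differential strength between samples $x, y$ is tested exactly:
$o_x \mid o_x+o_y \sim \mathrm{Bin}\!\left(o_x+o_y,\,
\lambda_x/(\lambda_x+\lambda_y)\right)$, one-sided toward $x$. See the
methods vignette (`vignettes/differential-loop-analysis.Rmd`) for the full
statistical account.

## Worked example

A small synthetic cohort (4 vs 4 samples, 12-Mb chromosome, 6 shared +
5 + 5 group-specific planted loops at 8-fold enrichment):

```r
library(loopdiffr)

cfg <- cohort_config(seed = 7, chrom_length = 1.2e7, depth = 4e6,
                     n_shared = 6, n_a_specific = 5, n_b_specific = 5,
                     n_cres = 100, n_genes = 200)
run <- run_full(analysis_config(n_perm = 500, seed = 7), cfg)

glance(run)
#> # A tibble: 1 × 10
#>   recovery_a recovery_b shared_reported n_enriched_a n_enriched_b     apa_p_a
#>        <dbl>      <dbl>           <int>        <int>        <int>       <dbl>
#> 1          1          1               0            5            5 0.000000145

run$consensus$A
#> <consensus_report> group A: 5 subtype-enriched loops (>= 2 samples)

round(run$apa$A$scores, 2)
#>   A1   A2   A3   A4   B1   B2   B3   B4
#> 2.58 2.70 2.52 2.61 1.30 1.16 1.33 1.31

run$apa$A$test
#> # A tibble: 1 × 5
#>   statistic    df     p_value mean_a mean_b
#> 1      24.7     6 0.000000145   2.60   1.28

glance(run$enrichment$A$A)
#> # A tibble: 1 × 5
#>   observed_fraction null_mean p_empirical n_perm  seed
#> 1                 1     0.104     0.00200    500   1008
```

Reading the numbers: all 5 planted A-specific loops were recovered in the
group-A report and none of the 6 shared loops leaked into either report
(`recovery_a = 1`, `shared_reported = 0`). A-enriched loops pile up to an
APA score of ~2.6 in group-A samples versus ~1.3 in group B — a one-sided
t test puts that contrast at p ≈ 1.5e-7. Every A-enriched loop has an
anchor in the A-group CRE set, against a permutation null averaging 10%
(p = 0.002 at 500 randomizations). Individual stages are available as
plain functions (`ice_balance()`, `compute_expected()`, `call_loops()`,
`pairwise_differential()`, `pileup()`, `compartment_eigenvector()`,
`permutation_enrichment()`, `link_genes()`,
`differential_expression()`) and accept external BEDPE/BED/TSV inputs via
`read_bedpe()`, `read_intervals()`, `read_contact_map()`,
`read_expression()`.

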