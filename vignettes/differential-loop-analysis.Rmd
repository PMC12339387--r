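---
title: "Differential chromatin loop analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential chromatin loop analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`loopdiffr` compares the three-dimensional chromatin architecture of two
sample groups — for example two tumour subtypes profiled by Hi-C — and asks
which chromatin loops are preferentially present in one group, how strong
that preference is in aggregate, whether the gained loops are anchored in a
given set of candidate regulatory elements (CREs) more often than chance,
and which genes with expression differences they may explain. This
vignette documents the statistical models, the tunable parameters, the
synthetic cohort the package ships for end-to-end validation, and the
design decisions taken where the problem left genuine latitude.

## From raw maps to balanced observed/expected

A per-sample cis contact map at resolution $r$ (10 kb throughout the loop
analysis) is a sparse upper-triangular matrix of counts $A_{ij}$. Two
standard transformations underlie everything else:

* **ICE balancing** (`ice_balance()`). Iterative correction finds bin
  biases $b_i$ such that the corrected matrix $A_{ij}/(b_i b_j)$ has equal
  marginals over mappable bins, iterating
  $b_i \leftarrow b_i \, m_i / \bar m$ until the maximum relative marginal
  deviation falls below `tol` ($10^{-5}$ by default, `max_iter` 200). A bin
  is *mappable* when its raw marginal is positive; unmappable bins get an
  undefined bias and are excluded from expected values, eigenvectors, APA
  and loop tests. Biases are rescaled to mean 1 over mappable bins — any
  fixed scale is equally valid, this one is stated for reproducibility.
* **Distance expectation** (`compute_expected()`). $e(d)$ is the mean
  balanced value over all mappable bin pairs at bin distance $d$,
  counting absent pixels as zero (sum over pixels divided by the number of
  mappable pairs, *not* by the number of stored pixels). Dividing a pixel
  by $e(d)$ gives its observed/expected (O/E) value; on a loop-free map
  the O/E is centred at 1 at every distance by construction.

## The loop caller

The paper-scale analysis this package generalises used an external
detector; `loopdiffr` ships its own documented caller so the pipeline is
self-contained, and accepts external BEDPE everywhere downstream
(`read_bedpe()` + `loops_to_bins()`).

`call_loops()` is a local-background test in the HiCCUPS family. For every
candidate pixel (O/E $\ge$ 1.5, anchor distance within 50 kb–2 Mb), the
local background is

$$\lambda_{\text{local}} = e(d) \cdot \max_k \widehat{OE}_k,$$

the distance expectation scaled by the largest mean O/E over six
neighborhoods between radii `bg_inner` = 2 and `bg_outer` = 5 bins: the
donut ring, the lower-left quadrant, and the four one-sided
horizontal/vertical stripes. Two details matter and are deliberate:

* **Stripes are split into their two sides.** Compartmentalised maps have
  sharp O/E regime changes at block boundaries; a two-sided stripe mixes
  regimes and mis-estimates the background in both directions. With
  one-sided stripes, at least one neighborhood always sits in the pixel's
  own regime, and the max rule then tracks the correct background.
* **The test propagates background-estimation noise.** The observed count
  is compared to the *raw-rescaled* background
  $\lambda_{\text{raw}} = \lambda_{\text{local}} b_i b_j$. A plain Poisson
  tail treats $\lambda_{\text{raw}}$ as known; because Poisson tails are
  steep, even a few percent of underestimation converts moderately
  surprising pixels into apparently extreme ones, and on loop-free
  simulated maps this inflates the family-wise false-call rate several
  fold. The default test is therefore the gamma–Poisson (negative
  binomial) predictive tail with shape equal to the effective information
  content of the winning neighborhood
  ($\text{shape} = \widehat{OE} \, N^2 / \sum_c 1/\mu_c$ over its $N$
  cells with raw expectations $\mu_c$); it reduces to the Poisson tail as
  the neighborhood information grows. `background_uncertainty = FALSE`
  restores the plain Poisson tail for users who prefer the textbook form.

Candidates whose $(2\,\texttt{bg\_outer}+1)^2$ box is more than
`max_sparsity` = 0.8 zeros are dropped (the sparsity guard against
artifactual enrichments in barren regions), p-values are BH-adjusted
across all tested pixels, and significant 8-connected pixels are merged,
keeping the pixel with the highest observed value (ties resolved to the
lexicographically smallest bin pair).

## Two-level differential consensus

Differential analysis follows a two-level support rule with the standard
thresholds: per-sample loop calls at FDR 0.05; each sample of one group
compared to *each* sample of the other at FDR 0.001; a loop is *gained*
for a sample when it is differential in at least `min_pairwise` = 2 of
those comparisons; loops gained in at least `min_samples` = 2 samples of a
group form that group's *subtype-enriched* set.

The pairwise test (`pairwise_differential()`) is a conditional binomial
rate comparison — the exact two-sample Poisson test: with raw-equivalent
observed counts $o_x, o_y$ and local backgrounds $\lambda_x, \lambda_y$ as
exposures, under the null of equal O/E rates
$o_x \mid o_x + o_y \sim \text{Bin}(o_x + o_y,\,
\lambda_x/(\lambda_x+\lambda_y))$, tested one-sided toward $x$, plus an
O/E ratio floor of 1.5. The matched pixel in $y$ is the highest-O/E pixel
within ±1 bin of the $x$ call — deliberately generous to $y$, which makes
the differential call conservative. Cross-sample loop identity uses a
±1-bin per-anchor tolerance with greedy matching (smallest total offset
first); representative coordinates of a consensus loop are its most
frequent exact coordinates, ties to the lexicographically smallest. All
of these tolerances are exposed (`tol_bins`, `min_ratio`, `fdr_diff`).

## APA, compartments, enrichment, genes

* **APA** (`pileup()`, `apa_score()`): O/E submatrices in a 5-bin window
  (50 kb × 50 kb at 10 kb) centred on each loop pixel are averaged
  element-wise; the APA score is the mean of the central 3 × 3. Loops
  whose window crosses a chromosome edge, touches the diagonal or
  overlaps a masked bin are skipped — these rules guarantee a finite O/E
  window and are stated because they are otherwise ambiguous. Group
  contrasts use a one-sided pooled-variance Student's t test
  (`compare_apa_groups()`; Welch by flag).
* **Compartments** (`compartment_eigenvector()`): per chromosome at 100 kb,
  the O/E matrix (clipped to $[0.01, 100]$ to tame sparse-bin outliers) is
  turned into a bin–bin Pearson correlation matrix; the eigenvector of the
  largest-magnitude eigenvalue, scaled by $\sqrt{|\lambda|}$, is the
  compartment track, sign-oriented against a phasing track (GC content in
  real data). Sample relatedness uses bins defined and nonzero in all
  samples, keeps the top 25% by cross-sample variance, and clusters
  $1 - r$ with average linkage; samples are ordered lexicographically
  before clustering so ties break deterministically.
* **CRE enrichment** (`permutation_enrichment()`): the observed statistic
  is the fraction of loops with *either* anchor overlapping a CRE
  (≥ 1 bp, half-open coordinates). Each of `n_perm` = 1,000 randomizations
  replaces every anchor with a uniformly placed interval of the same width
  on the same chromosome, preserving pairing; the one-sided empirical p
  uses the add-one estimator $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$,
  whose floor $1/(n_{perm}+1)$ matches the conventional "P < 0.001"
  reporting at 1,000 permutations.
* **Gene integration** (`link_genes()`, `differential_expression()`):
  genes are linked to a loop when the gene body extended by ±3 kb
  intersects either anchor (TSS-only mode by flag). Differential
  expression on FPKM uses a per-gene two-sided pooled-variance t test with
  $\log_2 FC = \log_2\frac{\bar x_A + \epsilon}{\bar x_B + \epsilon}$,
  $\epsilon = 0.1$ FPKM for stability near zero, and the standard
  significance rule $p < 0.05$ and $|\log_2 FC| \ge 1$.

## The synthetic cohort

`cohort_config()` / `simulate_cohort()` generate the study conditions the
package is validated under: two groups of 4 samples, one 50-Mb chromosome
at 10 kb (5,000 bins), expected depth $10^7$ cis pairs per sample. Pixel
counts are independent Poisson draws with mean

$$\lambda_{ij} = \text{depth} \cdot Z^{-1} (|i-j|+1)^{-\alpha}
  \cdot B_{ij} \cdot C_{ij},$$

with $\alpha = 1$ (the canonical contact-probability scaling),
$B_{ij}$ the planted-loop factor ($\varphi = 8$ at the loop pixel, Gaussian
spill $\sigma = 0.5$ bins — focal, essentially single-pixel loops), and
$C_{ij}$ a 100-kb compartment checkerboard factor (1.6 for same-label bin
pairs, its reciprocal otherwise). 40 shared and 30 + 30 group-specific
loops are planted with spans of 200 kb–1 Mb (enhancer–promoter scale) and
pairwise pixel separation beyond the detection/APA window. 20% of
compartment blocks flip label between the groups — that difference is what
lets eigenvector correlation clustering separate the groups, emulating the
subtype-level compartment divergence seen in real cohorts.

Loop anchors are restricted to active (+1) blocks whose label is the same
in both groups. This mirrors the biological predominance of
enhancer–promoter loops inside the A compartment, and it is also what
makes the truth labels meaningful: a "shared" loop has *identical*
expected contact in both groups, so any appearance in a differential
report is a genuine false positive, and group-specific loops carry a clean
$\varphi$-fold contrast undiluted by compartment context.

Expression tables place each gene's baseline at $\log_2$ FPKM
$\sim \mathcal N(5, 1)$; genes within ±3 kb of a group-specific anchor are
shifted by `expr_effect` = 2 in that group; all values get
$\mathcal N(0, 0.25^2)$ log-noise. Each group's CRE set puts half its 200
intervals at that group's specific anchors and the rest uniformly. A
phasing track of ±1 per block plus noise orients the eigenvectors.

What the generator does *not* emulate — restriction-fragment structure,
trans contacts, overdispersion beyond Poisson, copy-number effects,
structural-variant neo-loops, multi-chromosome genomes (the analysis
functions are multi-chromosome, the simulator is single-chromosome) — is
exactly what passing tests do not certify about real data. The cohort
demonstrates that the pipeline's statistics are calibrated and its
procedures recover planted structure under a known generative model; on
real Hi-C maps the Poisson assumption in particular is optimistic, which
is why the caller's background-uncertainty correction and the consensus
support thresholds matter.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on the default 50-Mb cohort
(about 2–3 minutes on one core), 200 loop-free replicates on 3-Mb maps for
the false-call rate, and 200 calibration replicates of the permutation
test at 1,000 randomizations each. The calibration study uses 250 loops
and 400 × 5 kb CREs: with the add-one estimator the rejection probability
at $\alpha$ can only be approached when the overlap-count distribution is
fine-grained (SD $\gtrsim 6$ counts); smaller sets make the test visibly
conservative through ties, which is a property of the estimator, not a
defect of the implementation.

Other numerical conventions, collected: coordinates are 0-based half-open
(BED) everywhere, overlap means ≥ 1 shared bp; contact maps are cis-only
and stored upper-triangular with duplicate keys summed; degenerate
inputs — already-balanced maps, empty maps, single-sample groups,
windows with no usable loops — raise errors rather than guessing;
a uniform O/E map yields an all-zero eigenvector flagged degenerate;
`compare_apa_groups()` returns $p = 0.5$ when both groups are constant
and equal (t = 0 by convention). Every stochastic step takes an explicit
seed and derives per-sample/per-replicate streams from it, so the full
cohort and every report are byte-reproducible from one integer.

## Known limitations

The caller is a documented stand-in, not a reimplementation of scale-space
detectors; very broad or nested loops are summarised by their strongest
pixel. The conditional binomial differential test conditions on total
counts and ignores replicate-level biological variance within groups — the
two-level support rule is the guard against sample idiosyncrasy. The
permutation null places anchors uniformly per chromosome without a
mappability mask (an optional mappable-restricted mode would sharpen it on
real genomes with large unmappable fractions). FPKM-based t tests are the
right tool only when raw counts are unavailable; with counts, use a
count-based DE framework and feed the results into `link_genes()`.
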