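---
title: "Methods and design notes for aimpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for aimpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aimpanel` evaluates biallelic ancestry-informative InDel panels and infers
biogeographic ancestry against continental reference populations. This
vignette records the models, estimator choices, numerical conventions and
known limitations — the decisions a maintainer would otherwise have to
reverse-engineer from the code.

## The data model

Everything operates on a `genotype_table`: a samples × loci matrix of
insertion-allele dosages (0/1/2, `NA` missing) with one population label per
sample. Dosage counts the **insertion** allele, matching the convention of
reporting insertion allele frequencies; the deletion frequency is `1 - p`.
Missing data policy, applied uniformly: per-locus statistics use observed
alleles only; the classifier skips an individual's missing loci; PCA
mean-imputes per locus; the admixture EM skips missing entries in both the
likelihood and the update sums. These are least-surprise choices (the
upstream desktop tools do not document theirs) and are stated in output
metadata rather than silently assumed.

## Forensic parameters and the exact validation surface

For genotype counts $(n_{II}, n_{ID}, n_{DD})$, $n$ observed diploids,
$p = (2n_{II} + n_{ID})/2n$:

* $H_o = n_{ID}/n$; $H_e = \frac{2n}{2n-1} 2pq$ — the **unbiased**
  (small-sample-corrected) estimator. The correction matters: at the
  bundled reference table's rarest locus the uncorrected value rounds to
  0.0554 only via the corrected formula, which is how the estimator choice
  was confirmed.
* $PIC = 2pq - 2p^2q^2$ (Botstein, two alleles); algebraically
  $PIC \le H_e$.
* $MP = \sum_g f_g^2$ over the three **observed** genotype frequencies;
  $PD = 1 - MP$.
* $TPI = 1/(2(1-H_o))$; $PE = H_o^2 (1 - 2 H_o (1-H_o)^2)$.

The package bundles a published 39-locus reference table (study sample of
509 Hui individuals) as its exact validation surface. Recomputing from the
*printed, rounded* $p$ and $H_o$ reproduces most but not all rows at 4
decimals (input rounding propagates into the 4th decimal in ~20% of rows).
`counts_from_summary()` therefore reconstructs the integer genotype counts
by rounding $H_o n$ and $2pn$ — asserting the parity self-consistency that
makes the reconstruction exact — and recomputation from those counts
reproduces **every** printed $H_e$, $PIC$, $TPI$, $PE$, $H_o$ and $MP$
value at 4 decimals. The acceptance tests use that route; the printed HWE
P values are not asserted because the upstream tool's test variant is
undocumented.

### Hardy–Weinberg testing

`hwe_test()` defaults to the conditional exact test: enumerate every
heterozygote count compatible with the observed allele counts (same
parity), weight by the Levene/Haldane conditional distribution (computed on
the log scale), and sum the probabilities of tables no more probable than
the observed one. No mid-P; a chi-square (1 df, no continuity correction)
alternative exists for comparison. Monomorphic loci return P = 1 with a
flag rather than an error. The exact test is validated against an
independent brute-force enumeration for every count triple with
$n \le 50$, and its rejection rate on panmictic simulated data at the
study's sample size (n = 509) sits inside binomial 99% bounds of the
nominal 0.05; at much smaller n the test is visibly conservative, which is
a property of exact tests, not a bug. Bonferroni correction flags
$P < \alpha/L$ over the $L$ tested loci.

## Differentiation statistics

**F_st.** One estimator is used everywhere: Weir & Cockerham's $\theta$
from the $a, b, c$ variance components with the observed-heterozygosity
term. Locus-wise $\theta = a/(a+b+c)$; multilocus is the ratio of sums.
Group-level comparisons pool individuals within a continent before the
two-population estimator (mirroring "populations of a continent considered
as a whole"). Negative estimates are reported as computed; a clamp flag
exists for display parity with published heat maps. The implementation is
tested against a second, independently transcribed rendering of the 1984
component formulas (dual-transcription oracle) to 1e-12 on random count
configurations, and recovers the Balding–Nichols $F$ parameter within
±0.03 at L = 500, n = 100 per group.

**Rosenberg's I_n.** Computed directly from the definition (nats), with
$0\ln 0 = 0$. The per-population PSD decomposition implemented is
$PSD_i = \frac{1}{K}\sum_j p_{ij}\ln(p_{ij}/\bar p_j)$ — non-negative terms
that sum exactly to $I_n$. The published pipeline converted PSD values with
the factor 0.693; since that factor equals $\ln 2$ the direction of the
conversion (nats↔bits) is ambiguous as described, so `convert_log_base()`
supports both directions explicitly and the informativeness table reports
both units rather than guessing the upstream tool's internal base.

**Nei's D_A.** $1 - \frac{1}{L}\sum_\ell \sum_j \sqrt{x_j y_j}$ over the
two InDel alleles; symmetric, zero diagonal, 1 iff no shared alleles.

## Naive-Bayes assignment with LOOCV

Training computes smoothed per-class insertion frequencies
$\hat p = (c + s)/(2n + 2s)$ with pseudo-count $s = 0.5$ per allele
(Jeffreys-style; configurable — the upstream tool's correction is
undocumented). Classification sums log HWE genotype probabilities
($\hat p^2, 2\hat p\hat q, \hat q^2$) over non-missing loci under equal
priors; ties break toward the lexicographically smallest label,
deterministically. LOOCV properly removes the left-out individual's
alleles from its own class before re-smoothing (a test verifies that
*improper* LOOCV dominates proper LOOCV on the diagonal, i.e. that removal
actually happens). Class granularity is whatever the table's labels are;
`pool_populations()` maps fine labels to continental groups.

## Admixture inference and ΔK

The published workflow ran STRUCTURE's MCMC (10,000 burn-in + 10,000
repetitions). This package fits the **same admixture likelihood** —
$\sum_{i\ell}[g\log(QP) + (2-g)\log(Q(1-P))]$ per allele copy,
uncorrelated frequencies — by EM to a maximum-likelihood point estimate,
as the ADMIXTURE program does. Rationale: a point estimate is what stacked
bar plots and mean-component summaries report, and EM is deterministic
given a seed, desk-scale, and property-testable (the log-likelihood is
provably non-decreasing per iteration, and the suite asserts it on every
fixture). Defaults: 10 seeded restarts keeping the best likelihood;
$P$ clipped to $[10^{-6}, 1-10^{-6}]$ each M-step so the likelihood stays
finite; convergence at $\Delta\ell < 10^{-6}$ or 500 iterations. K = 1 is
closed-form (pooled frequencies) so ΔK series can include it. Cluster
label switching across runs is resolved by greedy matching on the
correlation of cluster frequency vectors.

Supervised mode (`fit_supervised_q()`) fixes $P$ from labelled reference
populations and runs EM over Q only; that likelihood is concave in each Q
row, so a uniform start reaches the global maximum without restarts.

Evanno's ΔK is the restart-averaged absolute second difference of the
log-likelihood across K divided by the between-restart standard deviation;
zero SD raises a named degenerate error rather than returning infinity.

### Why the supervised-recovery criterion uses 500 loci

With the generating ancestry $(0.03, 0.08, 0.89, 0)$ and only 38 loci,
per-individual ML estimates are noisy (component SE ≈ 0.15) and truncated
at the simplex boundary; truncation inflates the small components and
deflates the dominant one, so the *mean* across 100 individuals is biased
(EAS ≈ 0.77 even when the true generating frequencies are supplied as the
reference). This is an estimator property, not an implementation defect:
at L = 500 well-differentiated loci — the stated design for the recovery
check — the same code recovers every component within ±0.05 (max error
≈ 0.03). The package therefore recovery-tests at L = 500 and documents
that a 38-locus panel supports qualitative ("EAS-dominant"), not
percentage-accurate, per-individual ancestry proportions.

## Ordination and trees

* **PCA**: per-locus mean imputation, column centring (optionally
  Patterson's $\sqrt{p(1-p)}$ standardisation), base-R SVD. Deterministic
  sign convention: each component's largest-magnitude loading is positive.
* **MDS**: classical Torgerson scaling implemented directly (double-centre
  the squared distances, scale top eigenvectors by root eigenvalues),
  chosen over the unstated desktop-tool algorithm for determinism; Kruskal
  stress-1 and any negative eigenvalues are reported so non-Euclidean
  input is visible. `stats::cmdscale` serves as the independent oracle in
  tests. The pipeline feeds it the pairwise F_st matrix (clamped at 0) —
  an assumption, documented, since the published figure's input
  dissimilarity is not stated.
* **NJ**: Saitou–Nei agglomeration with the standard Q criterion,
  deterministic lowest-index tie-break, three-point branch lengths at the
  final trifurcation; negative branch lengths kept unless clamped. Output
  is an `ape` `phylo`; `ape::nj` is the independent oracle, and a property
  test verifies NJ exactly inverts tree→additive-distance expansion on
  random 4–10 leaf trees.

## The synthetic world

`simulate_panel()` draws, per locus, an ancestral frequency
$p_0 \sim U(0.1, 0.9)$ (bounds configurable; the default mirrors an AIM
panel's ascertainment for informative loci), then per source group
$p_k \sim \mathrm{Beta}(p_0\frac{1-F}{F}, (1-p_0)\frac{1-F}{F})$ — the
Balding–Nichols model, whose $F$ is the expected F_st — and genotypes
$\sim \mathrm{Bin}(2, p_k)$. Admixed individuals draw each allele copy's
source independently from their Q vector, consistent with the admixture
likelihood fitted above. `make_world_fixture()` is the standard world:
AFR-like (F = 0.20), EUR-like (0.12), EAS-like (0.15), SAS-like (0.10), an
admixed AMR-like group (0.10/0.45/0.05/0.40) and a TARGET group
(0.03/0.08/0.89/0.00), 38 loci, 100 per group — the divergence and
admixture structure of a five-continent reference panel plus a
predominantly East Asian study group.

What the simulator does **not** emulate: linkage between loci (panel loci
are genome-dispersed by design), ascertainment correlated across
populations, genotyping error, and real 1000-Genomes-style substructure
within continents. A green test on this world therefore establishes that
the estimators recover the parameters of the stated generative model — not
that any particular real panel attains the published success ratios, which
would require the original reference genotypes.

## Numerical conventions and degenerate inputs

Seeds: every stochastic function takes an explicit seed; the pipeline
derives per-stage seeds from one root seed, so stages are individually
reproducible and two runs with identical seed and input produce
byte-identical statistic tables. Degenerate cases are named, classed
errors (`aimpanel_*`): all-missing locus, empty class, class of size 1 in
LOOCV, K exceeding the sample count, zero-SD ΔK, non-symmetric distance
inputs, < 3 leaves for NJ, < 2 samples for PCA. Monomorphic loci are
flagged, not errors, in HWE; both-monomorphic locus pairs yield NaN θ and
are excluded from threshold counts.

## Known limitations

* No permutation significance for F_st, no AMOVA, no bootstrap support on
  NJ trees (none reported in the workflow this replaces).
* The exact HWE test is conservative at small n; mid-P is deliberately not
  the default.
* Per-individual supervised ancestry at ~40 loci carries boundary bias
  (see above); report group means with that caveat, or use more loci.
* The VCF importer handles diploid GT biallelic indel records only and is
  a convenience path; the TSV dialect is canonical.
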