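# aimpanel

Statistical evaluation of small **ancestry-informative InDel (AIM-InDel)
panels** and biogeographic ancestry inference from them.

Forensic genetics increasingly uses compact panels of biallelic
insertion/deletion markers to infer the continental origin of a DNA donor:
the loci are chosen so their insertion-allele frequencies differ strongly
between continental populations, and they genotype cheaply on a capillary
electrophoresis platform. Evaluating such a panel, and analysing a study
population against continental references, requires a stack of classical
population-genetics machinery that is usually scattered across half a dozen
desktop tools (STRAF, Arlequin, Snipper, STRUCTURE + Harvester, Genepop,
DISPAN, MEGA). `aimpanel` implements that stack as one tested R package:

| Analysis | Functions |
|---|---|
| Allele frequencies, forensic parameters (MP, PD, PIC, PE, TPI, Ho, He), exact Hardy–Weinberg tests, Bonferroni correction | `forensic_table()`, `hwe_test()`, `bonferroni_correct()` |
| Weir–Cockerham F_st, locus-wise and multilocus | `wc_theta_locus()`, `multilocus_theta()`, `locus_fst_table()`, `pairwise_fst_matrix()` |
| Rosenberg's informativeness for assignment I_n with per-population PSD decomposition | `rosenberg_in()`, `psd_values()`, `informativeness_table()` |
| Nei's D_A genetic distance | `nei_da()`, `da_matrix()` |
| Snipper-style naive-Bayes population assignment with leave-one-out cross-validation | `train_frequencies()`, `classify()`, `loocv()` |
| Admixture-model ancestry proportions (EM, supervised and unsupervised) and Evanno ΔK | `fit_admixture()`, `fit_supervised_q()`, `admixture_series()`, `evanno_delta_k()` |
| Genotype PCA, classical MDS, neighbor-joining trees | `genotype_pca()`, `classical_mds()`, `neighbor_joining()` |
| Balding–Nichols simulation of divergent + admixed populations | `sim_config()`, `simulate_panel()`, `make_world_fixture()` |
| End-to-end pipeline with provenance manifest | `run_config()`, `run_all()`, `inst/cli/panel.R` |

## The core statistics

For a biallelic locus with insertion frequency *p* (*q* = 1 − *p*) and
genotype counts (*n*<sub>II</sub>, *n*<sub>ID</sub>, *n*<sub>DD</sub>) in *n*
diploids:

- Ho = *n*<sub>ID</sub>/*n*;  He = (2*n*/(2*n*−1))·2*pq* (Nei's unbiased
  estimator);  PIC = 2*pq* − 2*p*²*q*²
- MP = Σ<sub>g</sub> (genotype frequency)², PD = 1 − MP;
  TPI = 1/(2(1−Ho));  PE = Ho²(1 − 2·Ho·(1−Ho)²)
- Exact HWE P: conditional enumeration of heterozygote counts given allele
  counts (two-sided, no mid-P)
- F_st: Weir & Cockerham's θ from the a/b/c variance components; multilocus
  θ = Σa / Σ(a+b+c)
- I_n = Σ<sub>alleles</sub> [−p̄ ln p̄ + (1/K) Σ<sub>i</sub> p<sub>i</sub> ln p<sub>i</sub>]
  (nats), with PSD<sub>i</sub> = (1/K) Σ<sub>j</sub> p<sub>ij</sub> ln(p<sub>ij</sub>/p̄<sub>j</sub>) summing to I_n
- D_A = 1 − (1/L) Σ<sub>loci</sub> Σ<sub>alleles</sub> √(x y)
- Admixture: maximise Σ log[Σ<sub>k</sub> q<sub>ik</sub> p<sub>kℓ</sub>] per
  allele copy by EM (the likelihood STRUCTURE's admixture model uses, fitted
  as a point estimate); ΔK = mean|L″(K)| / sd(L(K))

## Worked example

```r
library(aimpanel)

# a synthetic world: 4 continental reference groups, one admixed
# "AMR-like" group, and a target group with ancestry (3% AFR, 8% EUR,
# 89% EAS) -- 38 loci, 100 individuals per group
sim <- make_world_fixture(seed = 7)

# supervised ancestry of the target group against the 4 references
refs <- subset_table(sim$table,
                     samples = !(sim$table$population %in% c("TARGET", "AMR-like")))
Q <- fit_supervised_q(subset_table(sim$table,
                                   samples = sim$table$population == "TARGET"),
                      population_frequencies(refs))
round(colMeans(Q), 4)
#> AFR-like EAS-like EUR-like SAS-like
#>   0.0726   0.7492   0.0964   0.0818

# leave-one-out cross-validated assignment of the reference groups
conf <- loocv(subset_table(sim$table, samples = sim$table$population != "TARGET"))
round(100 * success_ratios(conf), 0)
#> AFR-like AMR-like EAS-like EUR-like SAS-like
#>       97       61       99       87       85
```

The target group is correctly dominated by its East Asian-like source; at
38 loci the per-individual maximum-likelihood estimates are noisy and
boundary-truncated, so the mean EAS component (0.75) understates the
generating 0.89 — at L = 500 loci the same estimator recovers it within
±0.03 (see the methods vignette). The admixed AMR-like group is, as
expected, by far the hardest class to re-assign (61% success), while the
four unadmixed references classify at 85–99%.

A published 39-locus reference table (509-individual Hui study sample) is
bundled; reconstructing integer genotype counts from its printed (p, Ho, n)
and recomputing everything reproduces all printed He, PIC, TPI, PE and MP
values exactly at 4 decimals:

```r
ft <- forensic_table(hui_reference_table())
round(as.numeric(ft[ft$locus == "rs5896844", c("MP","PIC","PE","TPI","Ho","He")]), 4)
#> 0.8992 0.0538 0.0022 0.5258 0.0491 0.0554
```

## Command line

```sh
Rscript inst/cli/panel.R simulate --seed 1 --out world.tsv
Rscript inst/cli/panel.R run-all --in world.tsv --target-group TARGET --out results/
```

Subcommands: `simulate forensic hwe informativeness fst da classify
admixture deltak pca mds njtree run-all`.
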