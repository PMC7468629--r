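Package: aimpanel
Title: Evaluation of Ancestry-Informative InDel Panels and Biogeographic
    Ancestry Inference
Version: 0.1.0
Authors@R:
    person("aimpanel", "developers", email = "aimpanel@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for evaluating small panels of
    biallelic ancestry-informative insertion/deletion (InDel) markers and
    for inferring biogeographic ancestry from them.  Implements per-locus
    allele frequencies, forensic parameters (matching probability, power
    of discrimination, polymorphic information content, power of
    exclusion, typical paternity index, observed and unbiased expected
    heterozygosity) with exact Hardy-Weinberg tests and Bonferroni
    correction; Weir-Cockerham F_st (locus-wise and multilocus),
    Rosenberg's informativeness for assignment, and Nei's D_A distance;
    naive-Bayes population assignment with leave-one-out cross-validation;
    maximum-likelihood admixture inference (EM) with Evanno delta-K model
    selection; genotype PCA, classical MDS, and neighbor-joining trees;
    and a Balding-Nichols simulator for divergent and admixed populations
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
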