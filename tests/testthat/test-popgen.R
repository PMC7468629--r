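# Forensic parameter machinery; the published 39-locus table is the
# exact validation surface (see test-acceptance.R for the full sweep).

test_that("allele frequency, Ho and the rarest-locus published row", {
  # (2, 25, 482) is the reconstructed genotype composition of the panel's
  # least polymorphic locus in the n=509 study sample
  af <- allele_frequency(c(2, 25, 482))
  expect_equal(af$p, 29 / 1018)
  expect_equal(round(af$p, 4), 0.0285)
  expect_equal(round(observed_heterozygosity(c(2, 25, 482)), 4), 0.0491)
  expect_equal(allele_frequency(c(0, 0, 10))$p, 0)
  expect_equal(allele_frequency(c(5, 0, 5))$p, 0.5)
  expect_equal(observed_heterozygosity(c(10, 0, 10)), 0)
  expect_equal(observed_heterozygosity(c(0, 20, 0)), 1)
  expect_error(allele_frequency(c(0, 0, 0)), class = "aimpanel_degenerate_locus")
})

test_that("He, PIC, MP/PD, PE, TPI formulas reproduce published spot values", {
  expect_equal(round(expected_heterozygosity_unbiased(0.0285, 509), 4), 0.0554)
  expect_equal(round(expected_heterozygosity_unbiased(0.4872, 509), 4), 0.5002)
  expect_equal(expected_heterozygosity_unbiased(0, 100), 0)
  expect_equal(round(pic_biallelic(0.0285), 4), 0.0538)
  expect_equal(round(pic_biallelic(0.4872), 4), 0.3748)
  expect_equal(pic_biallelic(0.5), 0.375)
  mp <- match_probability(c(2, 25, 482))
  expect_equal(unname(mp["MP"] + mp["PD"]), 1)
  expect_lt(abs(mp[["MP"]] - 0.8992), 1.0001e-4)
  expect_equal(unname(match_probability(c(0, 0, 7))), c(1, 0))
  expect_equal(match_probability(c(3, 3, 3))[["MP"]], 1 / 3)
  expect_equal(round(power_of_exclusion(0.0491), 4), 0.0022)
  expect_equal(round(power_of_exclusion(0.5422), 4), 0.2272)
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(round(typical_paternity_index(0.0491), 4), 0.5258)
  expect_equal(round(typical_paternity_index(0.2554), 4), 0.6715)
  expect_equal(typical_paternity_index(0), 0.5)
})

test_that("forensic identities hold on random genotype counts", {
  set.seed(11)
  for (rep in 1:50) {
    cts <- random_counts()
    af <- allele_frequency(cts)
    ho <- observed_heterozygosity(cts)
    mp <- match_probability(cts)
    expect_equal(unname(mp["MP"] + mp["PD"]), 1)
    if (ho < 1)
      expect_equal(typical_paternity_index(ho) * 2 * (1 - ho), 1)
    # PIC <= He (algebraic, biallelic); He/PIC symmetric in p <-> 1-p,
    # maximised at 0.5
    expect_lte(pic_biallelic(af$p),
               expected_heterozygosity_unbiased(af$p, af$n) + 1e-12)
    expect_equal(pic_biallelic(af$p), pic_biallelic(1 - af$p))
    expect_equal(expected_heterozygosity_unbiased(af$p, af$n),
                 expected_heterozygosity_unbiased(1 - af$p, af$n))
    expect_lte(pic_biallelic(af$p), pic_biallelic(0.5))
  }
})

test_that("exact HWE test equals the brute-force enumeration oracle", {
  expect_equal(hwe_test(c(25, 50, 25))$p_value, hwe_brute_force(c(25, 50, 25)))
  expect_equal(hwe_test(c(10, 0, 10))$p_value, hwe_brute_force(c(10, 0, 10)))
  set.seed(5)
  for (rep in 1:200) {
    cts <- random_counts(30L)
    expect_equal(hwe_test(cts)$p_value, hwe_brute_force(cts),
                 tolerance = 1e-10)
  }
})

test_that("HWE edge cases: perfect proportions and monomorphic loci", {
  res <- hwe_test(c(25, 50, 25), method = "chi2")
  expect_equal(res$p_value, 1)
  expect_false(res$monomorphic)
  mono <- hwe_test(c(0, 0, 12))
  expect_equal(mono$p_value, 1)
  expect_true(mono$monomorphic)
  expect_true(hwe_test(c(12, 0, 0), method = "chi2")$monomorphic)
})

test_that("exact HWE rejection rate is calibrated on panmictic data", {
  # Balding-Nichols world with a single panmictic population: loci are
  # independent HWE draws, so raw-alpha rejections should be binomial(L, a)
  # up to the exact test's discreteness; n = 509 (the panel's study-sample
  # size) keeps discreteness mild.
  set.seed(97)
  L <- 2000L
  p <- runif(L, 0.1, 0.9)
  rej <- 0L
  for (l in seq_len(L)) {
    g <- rbinom(509L, 2L, p[l])
    cts <- c(sum(g == 2L), sum(g == 1L), sum(g == 0L))
    if (hwe_test(cts)$p_value < 0.05) rej <- rej + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), L, 0.05) / L
  expect_gte(rej / L, bounds[1])
  expect_lte(rej / L, bounds[2])
})

test_that("Bonferroni correction flags p < alpha/L", {
  ref <- hui_forensic_reference()
  bc <- bonferroni_correct(ref$P, alpha = 0.05)
  expect_equal(bc$alpha_adjusted, 0.05 / 39)
  expect_equal(sum(bc$significant), 0L)
  expect_true(bonferroni_correct(0.001)$significant)
  expect_length(bonferroni_correct(numeric(0))$significant, 0L)
})

test_that("forensic_table produces one row per locus plus a means row", {
  g <- fixed_opposite_table(n_per = 8L, L = 3L)
  # replace with a polymorphic single-population table
  set.seed(2)
  d <- matrix(rbinom(60, 2, 0.4), 20, 3,
              dimnames = list(sprintf("s%02d", 1:20), c("a", "b", "c")))
  tab <- genotype_table(d, population = rep("P", 20))
  ft <- forensic_table(tab)
  expect_equal(nrow(ft), 4L)
  expect_equal(ft$locus[4], "Mean")
  expect_equal(as.numeric(ft$PIC[4]), mean(as.numeric(ft$PIC[1:3])))
  # single-locus table: means row equals the locus row
  ft1 <- forensic_table(subset_table(tab, loci = "a"))
  expect_equal(as.numeric(ft1[2, -1]), as.numeric(ft1[1, -1]))
})

test_that("summary-count reconstruction is self-consistent on the reference", {
  ref <- hui_forensic_reference()
  for (i in seq_len(nrow(ref))) {
    cts <- counts_from_summary(ref$insertion[i], ref$Ho[i], 509L)
    expect_equal(sum(cts), 509L)
    expect_equal(cts[2], round(ref$Ho[i] * 509))
  }
  # odd allele/heterozygote difference is rejected
  expect_error(counts_from_summary(0.5, 0.5, 10),
               class = "aimpanel_inconsistent_summary")
})
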