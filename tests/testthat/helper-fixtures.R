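# Small in-code fixtures shared across test files.

# two-population table with loci fixed for opposite alleles
fixed_opposite_table <- function(n_per = 10L, L = 5L) {
  dosage <- rbind(matrix(2L, n_per, L), matrix(0L, n_per, L))
  genotype_table(dosage, population = rep(c("A", "B"), each = n_per),
                 sample_id = sprintf("s%02d", seq_len(2L * n_per)),
                 locus_id = sprintf("L%d", seq_len(L)))
}

# random valid genotype-count triple with at least one observation
random_counts <- function(max_n = 40L) {
  n <- sample.int(max_n, 1L)
  as.integer(rmultinom(1L, n, prob = runif(3, 0.05, 1)))
}

# independent transcription of the two-population Weir-Cockerham (1984)
# variance components, written from the component formulas directly
# (r = 2); used as the dual-transcription oracle.
wc_theta_oracle <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[1] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[1] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1
  h2 <- c2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# brute-force exact HWE oracle: enumerate every genotype table compatible
# with the observed allele counts, weight by the conditional multinomial
# probability, and sum tables no more probable than the observed one.
hwe_brute_force <- function(counts) {
  n <- sum(counts)
  n_ins <- 2 * counts[1] + counts[2]
  nii_max <- floor(n_ins / 2)
  tabs <- lapply(0:nii_max, function(nii) {
    nid <- n_ins - 2 * nii
    ndd <- n - nii - nid
    if (ndd < 0) NULL else c(nii, nid, ndd)
  })
  tabs <- Filter(Negate(is.null), tabs)
  w <- vapply(tabs, function(ct)
    factorial(n) / (factorial(ct[1]) * factorial(ct[2]) * factorial(ct[3])) *
      2^ct[2], 0)
  prob <- w / sum(w)
  obs <- prob[vapply(tabs, function(ct) ct[2] == counts[2], TRUE)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}
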