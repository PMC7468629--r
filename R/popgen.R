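#' Insertion allele frequency from genotype counts
#'
#' @param counts integer vector `c(n_ii, n_id, n_dd)` of insertion
#'   homozygote, heterozygote and deletion homozygote counts at one locus.
#' @return list with `p` (insertion frequency), `n` (observed diploid
#'   count) and `counts`.
#' @export
allele_frequency <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L)
    aim_stop("degenerate_locus", "all genotypes missing at this locus")
  list(p = (2 * counts[1L] + counts[2L]) / (2 * n), n = n, counts = counts)
}

check_counts <- function(counts) {
  counts <- as.integer(round(counts))
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0L))
    aim_stop("bad_counts", "counts must be 3 non-negative integers (n_ii, n_id, n_dd)")
  counts
}

#' Observed heterozygosity
#' @inheritParams allele_frequency
#' @return fraction of heterozygous individuals among observed genotypes.
#' @export
observed_heterozygosity <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L) aim_stop("degenerate_locus", "all genotypes missing")
  counts[2L] / n
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected estimator `He = 2n/(2n-1) * 2p(1-p)` for a
#' biallelic locus.
#'
#' @param p insertion allele frequency.
#' @param n diploid sample count.
#' @export
expected_heterozygosity_unbiased <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  (2 * n / (2 * n - 1)) * 2 * p * (1 - p)
}

#' Polymorphic information content (biallelic)
#'
#' Botstein's PIC specialised to two alleles: `PIC = 2pq - 2p^2 q^2`.
#'
#' @param p insertion allele frequency.
#' @export
pic_biallelic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  2 * p * q - 2 * p^2 * q^2
}

#' Matching probability and power of discrimination
#'
#' `MP` is the sum of squared observed genotype frequencies over the three
#' genotype classes; `PD = 1 - MP`.
#'
#' @inheritParams allele_frequency
#' @return named vector `c(MP, PD)`.
#' @export
match_probability <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L) aim_stop("degenerate_locus", "all genotypes missing")
  mp <- sum((counts / n)^2)
  c(MP = mp, PD = 1 - mp)
}

#' Power of exclusion
#'
#' Brenner's formula from observed heterozygosity:
#' `PE = h^2 (1 - 2 h H^2)` with `h = Ho`, `H = 1 - Ho`.
#'
#' @param ho observed heterozygosity.
#' @export
power_of_exclusion <- function(ho) {
  stopifnot(all(ho >= 0 & ho <= 1))
  H <- 1 - ho
  ho^2 * (1 - 2 * ho * H^2)
}

#' Typical paternity index
#'
#' `TPI = 1 / (2 (1 - Ho))`.
#'
#' @param ho observed heterozygosity (must be < 1).
#' @export
typical_paternity_index <- function(ho) {
  stopifnot(all(ho >= 0 & ho < 1))
  1 / (2 * (1 - ho))
}

#' Hardy-Weinberg equilibrium test for one biallelic locus
#'
#' The exact test conditions on the observed allele counts and sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed table (two-sided, no mid-P).  The
#' chi-square alternative is the 1-df goodness-of-fit test without
#' continuity correction.
#'
#' @inheritParams allele_frequency
#' @param method `"exact"` (default) or `"chi2"`.
#' @return list with `p_value`, `method`, `monomorphic` flag.
#' @export
hwe_test <- function(counts, method = c("exact", "chi2")) {
  method <- match.arg(method)
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L) aim_stop("degenerate_locus", "all genotypes missing")
  n_ins <- 2L * counts[1L] + counts[2L]
  if (n_ins == 0L || n_ins == 2L * n)
    return(list(p_value = 1, method = method, monomorphic = TRUE))
  p_value <- if (method == "exact") hwe_exact_p(counts) else hwe_chi2_p(counts)
  list(p_value = p_value, method = method, monomorphic = FALSE)
}

# Conditional exact distribution of the heterozygote count given allele
# counts (Levene/Haldane); probabilities computed on the log scale.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_ins <- 2L * counts[1L] + counts[2L]
  n_rare <- min(n_ins, 2L * n - n_ins)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  n_rr <- (n_rare - hets) / 2L
  n_cc <- n - n_rr - hets
  logp <- lfactorial(n) - lfactorial(n_rr) - lfactorial(hets) -
    lfactorial(n_cc) + hets * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(counts[2L], hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

hwe_chi2_p <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Bonferroni correction for per-locus HWE tests
#'
#' @param p_values numeric vector of raw P values.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `alpha_adjusted` (`alpha / L`) and logical
#'   `significant` flags (`p < alpha / L`).
#' @export
bonferroni_correct <- function(p_values, alpha = 0.05) {
  L <- length(p_values)
  if (L == 0L) return(list(alpha_adjusted = numeric(0), significant = logical(0)))
  list(alpha_adjusted = alpha / L, significant = p_values < alpha / L)
}

#' Per-locus forensic parameter table
#'
#' Computes, for every locus of a genotype table: insertion and deletion
#' allele frequencies, matching probability (MP), power of discrimination
#' (PD), polymorphic information content (PIC), power of exclusion (PE),
#' typical paternity index (TPI), observed (Ho) and unbiased expected (He)
#' heterozygosity, and the Hardy-Weinberg P value; plus an unweighted
#' `Mean` row across loci.
#'
#' @param x a [genotype_table()].
#' @param hwe_method passed to [hwe_test()].
#' @return data frame with one row per locus and a final `Mean` row
#'   (the `P` column mean is reported but rarely meaningful).
#' @export
forensic_table <- function(x, hwe_method = "exact") {
  stopifnot(inherits(x, "genotype_table"))
  cnt <- locus_counts(x)
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    cts <- cnt[i, ]
    af <- allele_frequency(cts)
    ho <- observed_heterozygosity(cts)
    mp <- match_probability(cts)
    data.frame(locus = rownames(cnt)[i],
               MP = mp[["MP"]], PD = mp[["PD"]],
               PIC = pic_biallelic(af$p),
               PE = power_of_exclusion(ho),
               TPI = typical_paternity_index(ho),
               Ho = ho,
               He = expected_heterozygosity_unbiased(af$p, af$n),
               P = hwe_test(cts, hwe_method)$p_value,
               insertion = af$p, deletion = 1 - af$p,
               n = af$n)
  })
  out <- do.call(rbind, rows)
  num <- vapply(out[-1L], is.numeric, TRUE)
  means <- c(locus = "Mean", as.list(colMeans(out[-1L][num])))
  out <- rbind(out, as.data.frame(means))
  rownames(out) <- NULL
  out
}

#' Reconstruct genotype counts from published summary values
#'
#' Given a printed insertion frequency `p`, observed heterozygosity `ho`
#' and diploid sample size `n` (all rounded in publication), recovers the
#' integer genotype counts by rounding `ho * n` and `p * 2n`, asserting
#' self-consistency (the insertion-allele count minus the heterozygote
#' count must be even and all counts non-negative).
#'
#' @param p published insertion allele frequency.
#' @param ho published observed heterozygosity.
#' @param n diploid sample count.
#' @return integer vector `c(n_ii, n_id, n_dd)`.
#' @export
counts_from_summary <- function(p, ho, n) {
  n_het <- round(ho * n)
  n_ins <- round(p * 2 * n)
  if ((n_ins - n_het) %% 2 != 0)
    aim_stop("inconsistent_summary",
             "rounded allele count %d and heterozygote count %d have odd difference",
             n_ins, n_het)
  n_ii <- (n_ins - n_het) / 2
  n_dd <- n - n_ii - n_het
  if (n_ii < 0 || n_dd < 0)
    aim_stop("inconsistent_summary", "negative reconstructed genotype count")
  as.integer(c(n_ii, n_het, n_dd))
}

#' Bundled reference forensic table
#'
#' The published per-locus summary (allele frequencies, forensic
#' parameters, HWE P values) of the 39-locus AIM-InDel panel genotyped in
#' a study sample of 509 Hui individuals; used as the package's exact
#' validation surface.
#'
#' @return data frame with columns `locus`, `MP`, `PD`, `PIC`, `PE`,
#'   `TPI`, `Ho`, `He`, `P`, `insertion`, `deletion`.
#' @export
hui_forensic_reference <- function() {
  utils::read.delim(system.file("extdata", "hui_forensic_reference.tsv",
                                package = "aimpanel"),
                    stringsAsFactors = FALSE)
}

#' Rebuild a Hui-like genotype table from the bundled reference summary
#'
#' Reconstructs per-locus genotype counts with [counts_from_summary()] and
#' lays them out as a single-population genotype table (genotype order
#' within the sample column is arbitrary and does not affect any per-locus
#' statistic).
#'
#' @param n diploid sample size of the published study group.
#' @return a [genotype_table()] with one population `"HUI"`.
#' @export
hui_reference_table <- function(n = 509L) {
  ref <- hui_forensic_reference()
  dosage <- vapply(seq_len(nrow(ref)), function(i) {
    cts <- counts_from_summary(ref$insertion[i], ref$Ho[i], n)
    rep(c(2L, 1L, 0L), times = cts)
  }, integer(n))
  colnames(dosage) <- ref$locus
  genotype_table(dosage, population = rep("HUI", n),
                 sample_id = sprintf("HUI%03d", seq_len(n)))
}
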