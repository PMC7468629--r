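#' Weir-Cockerham variance components for one biallelic locus
#'
#' Computes the among-population (a), among-individual (b) and
#' within-individual (c) variance components of Weir & Cockerham's (1984)
#' theta from per-population genotype counts, using the observed
#' heterozygosity term.
#'
#' @param counts_list list of genotype-count triples `c(n_ii, n_id, n_dd)`,
#'   one per population.
#' @return named vector `c(a, b, c)`.
#' @keywords internal
wc_components <- function(counts_list) {
  r <- length(counts_list)
  stopifnot(r >= 2L)
  n_i <- vapply(counts_list, sum, 0)
  if (any(n_i == 0))
    aim_stop("degenerate_locus", "a population has no observed genotypes")
  p_i <- vapply(counts_list, function(ct) (2 * ct[1L] + ct[2L]) / (2 * sum(ct)), 0)
  h_i <- vapply(counts_list, function(ct) ct[2L] / sum(ct), 0)
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

#' Locus-wise Weir-Cockerham theta for two populations
#'
#' @param counts_x,counts_y genotype-count triples for the two populations
#'   at one biallelic locus.
#' @return theta-hat `a / (a + b + c)`; may be slightly negative; `NaN`
#'   when both populations are monomorphic for the same allele (zero
#'   denominator).
#' @export
wc_theta_locus <- function(counts_x, counts_y) {
  comp <- wc_components(list(check_counts(counts_x), check_counts(counts_y)))
  denom <- sum(comp)
  if (denom == 0) return(NaN)
  comp[["a"]] / denom
}

#' Multilocus Weir-Cockerham theta between two populations
#'
#' Ratio-of-sums estimator `sum(a) / sum(a + b + c)` over loci; loci where
#' both populations are monomorphic contribute zero to both sums.
#'
#' @param x a [genotype_table()].
#' @param pop_x,pop_y population labels.
#' @param loci optional locus subset (ids).
#' @export
multilocus_theta <- function(x, pop_x, pop_y, loci = NULL) {
  if (!is.null(loci)) x <- subset_table(x, loci = loci)
  cx <- locus_counts(x, pop_x)
  cy <- locus_counts(x, pop_y)
  comps <- vapply(seq_len(nrow(cx)), function(i)
    wc_components(list(cx[i, ], cy[i, ])), c(a = 0, b = 0, c = 0))
  sum(comps["a", ]) / sum(comps)
}

#' Population-pairwise multilocus F_st matrix
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset.
#' @param clamp_negative set slightly negative estimates to zero (display
#'   parity with published heat maps); default keeps them as computed.
#' @return symmetric populations x populations matrix with zero diagonal.
#' @export
pairwise_fst_matrix <- function(x, loci = NULL, clamp_negative = FALSE) {
  if (!is.null(loci)) x <- subset_table(x, loci = loci)
  pops <- sort(unique(x$population))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    th <- multilocus_theta(x, pops[i], pops[j])
    if (clamp_negative && is.finite(th)) th <- max(th, 0)
    m[i, j] <- m[j, i] <- th
  }
  m
}

#' Locus-wise pairwise F_st table across population groups
#'
#' One row per locus, one column per unordered pair of population labels
#' (individuals pooled by label first, so passing continental labels
#' reproduces group-level comparisons).
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset.
#' @return numeric matrix loci x pairs, columns named `"A-B"`.
#' @export
locus_fst_table <- function(x, loci = NULL) {
  if (!is.null(loci)) x <- subset_table(x, loci = loci)
  pops <- sort(unique(x$population))
  counts <- lapply(pops, function(p) locus_counts(x, p))
  names(counts) <- pops
  pairs <- utils::combn(pops, 2L)
  out <- matrix(NA_real_, length(x$locus_id), ncol(pairs),
                dimnames = list(x$locus_id,
                                apply(pairs, 2L, paste, collapse = "-")))
  for (k in seq_len(ncol(pairs))) {
    ca <- counts[[pairs[1L, k]]]
    cb <- counts[[pairs[2L, k]]]
    out[, k] <- vapply(seq_len(nrow(ca)), function(i)
      wc_theta_locus(ca[i, ], cb[i, ]), 0)
  }
  out
}

#' Count loci exceeding an F_st threshold, per population pair
#'
#' @param fst_table loci x pairs matrix from [locus_fst_table()].
#' @param threshold F_st cutoff (exceedance is strict, `theta > threshold`).
#' @return named integer vector of counts per pair (NaN loci ignored).
#' @export
count_loci_above <- function(fst_table, threshold = 0.25) {
  colSums(fst_table > threshold, na.rm = TRUE)
}

#' Rosenberg's informativeness for assignment (I_n) at one locus
#'
#' For K populations with biallelic insertion frequencies `p`,
#' `I_n = sum_j [ -pbar_j ln pbar_j + (1/K) sum_i p_ij ln p_ij ]` over the
#' two alleles, with the unweighted mean `pbar_j` and `0 ln 0 = 0`.
#' Returned in nats; see [convert_log_base()] for bit conversion.
#'
#' @param p numeric vector of per-population insertion frequencies.
#' @return I_n in nats (non-negative, at most `log(K)`).
#' @export
rosenberg_in <- function(p) {
  stopifnot(all(p >= 0 & p <= 1), length(p) >= 2L)
  freqs <- rbind(p, 1 - p)            # alleles x populations
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  pbar <- rowMeans(freqs)
  sum(-xlx(pbar) + rowMeans(xlx(freqs)))
}

#' Per-population divergence decomposition of I_n
#'
#' Splits I_n additively across populations as the scaled Kullback-Leibler
#' divergence of each population's allele frequencies from the unweighted
#' mean: `PSD_i = (1/K) sum_j p_ij ln(p_ij / pbar_j)`.  The values are
#' non-negative and sum to [rosenberg_in()].
#'
#' @inheritParams rosenberg_in
#' @return numeric vector of per-population PSD values (nats).
#' @export
psd_values <- function(p) {
  stopifnot(all(p >= 0 & p <= 1), length(p) >= 2L)
  K <- length(p)
  freqs <- rbind(p, 1 - p)
  pbar <- rowMeans(freqs)
  contrib <- ifelse(freqs > 0, freqs * log(freqs / pbar), 0)
  colSums(contrib) / K
}

#' Convert an information value between logarithm bases
#'
#' Multiplies by `log(from_base) / log(to_base)`; e.g. nats to bits with
#' `from_base = exp(1), to_base = 2` (factor 1/ln 2 = 1.4427) and bits to
#' nats with the reverse (factor ln 2 = 0.6931).
#'
#' @param value numeric value(s).
#' @param from_base,to_base logarithm bases.
#' @export
convert_log_base <- function(value, from_base, to_base) {
  value * log(from_base) / log(to_base)
}

#' Per-locus informativeness table across population groups
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset.
#' @return data frame: locus, I_n in nats, I_n in bits, and one PSD column
#'   per population (nats).
#' @export
informativeness_table <- function(x, loci = NULL) {
  freqs <- population_frequencies(x, loci = loci)   # pops x loci
  in_nats <- apply(freqs, 2L, rosenberg_in)
  psd <- t(apply(freqs, 2L, psd_values))
  colnames(psd) <- paste0("PSD_", rownames(freqs))
  data.frame(locus = colnames(freqs), In_nats = in_nats,
             In_bits = convert_log_base(in_nats, exp(1), 2),
             psd, row.names = NULL)
}

#' Nei's D_A distance between two populations
#'
#' `D_A = 1 - (1/L) sum_loci sum_alleles sqrt(x_j y_j)` (Nei, Tajima &
#' Tateno 1983), here over the two InDel alleles.
#'
#' @param freq_x,freq_y per-locus insertion frequencies of the two
#'   populations (equal length).
#' @export
nei_da <- function(freq_x, freq_y) {
  stopifnot(length(freq_x) == length(freq_y), length(freq_x) >= 1L)
  1 - mean(sqrt(freq_x * freq_y) + sqrt((1 - freq_x) * (1 - freq_y)))
}

#' Population-pairwise Nei D_A matrix
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset.
#' @return symmetric populations x populations matrix, zero diagonal.
#' @export
da_matrix <- function(x, loci = NULL) {
  freqs <- population_frequencies(x, loci = loci)
  pops <- rownames(freqs)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- nei_da(freqs[i, ], freqs[j, ])
  }
  m
}
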