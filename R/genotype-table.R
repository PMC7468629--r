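#' Genotype table of insertion dosages
#'
#' The universal input container: a samples x loci matrix of insertion
#' allele dosages (0, 1, 2 copies of the insertion allele, `NA` for a
#' missing genotype) together with one population label per sample.
#'
#' @param dosage integer matrix, samples in rows, loci in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param population character vector, one label per sample.
#' @param sample_id unique sample identifiers; defaults to the rownames
#'   of `dosage`.
#' @param locus_id unique locus identifiers (e.g. rs numbers); defaults
#'   to the colnames of `dosage`.
#' @return An object of class `genotype_table` with fields `dosage`,
#'   `sample_id`, `population`, `locus_id`.
#' @examples
#' g <- genotype_table(rbind(a = c(l1 = 2, l2 = 1), b = c(0, NA)),
#'                     population = c("P1", "P2"))
#' g
#' @export
genotype_table <- function(dosage, population, sample_id = rownames(dosage),
                           locus_id = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(locus_id)) locus_id <- paste0("L", seq_len(ncol(dosage)))
  sample_id <- as.character(sample_id)
  locus_id <- as.character(locus_id)
  population <- as.character(population)
  if (anyDuplicated(sample_id))
    aim_stop("duplicate_sample_id", "duplicate sample id(s): %s",
             paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (anyDuplicated(locus_id))
    aim_stop("duplicate_locus_id", "duplicate locus id(s): %s",
             paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  if (length(population) != nrow(dosage))
    aim_stop("bad_population_labels",
             "need exactly one population label per sample (%d labels, %d samples)",
             length(population), nrow(dosage))
  if (length(sample_id) != nrow(dosage) || length(locus_id) != ncol(dosage))
    aim_stop("bad_dimensions", "id vectors do not match dosage dimensions")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    aim_stop("bad_dosage", "dosage entries must be 0, 1, 2 or NA (found %s)",
             paste(unique(dosage[bad]), collapse = ", "))
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_id, locus_id)
  structure(list(dosage = dosage, sample_id = sample_id,
                 population = population, locus_id = locus_id),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  tab <- table(x$population)
  cat(sprintf("genotype_table: %d samples x %d loci, %d population(s)\n",
              length(x$sample_id), length(x$locus_id), length(tab)))
  cat(paste(sprintf("  %s: n=%d", names(tab), as.integer(tab)), collapse = "\n"),
      "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Subset a genotype table
#'
#' @param x a [genotype_table()].
#' @param loci locus ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param samples sample ids (or index) to keep; `NULL` keeps all.
#' @param drop_loci locus ids to drop (applied after `loci`); convenient for
#'   per-analysis exclusion lists.
#' @return a new `genotype_table`.
#' @export
subset_table <- function(x, loci = NULL, samples = NULL, drop_loci = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  li <- if (is.null(loci)) seq_along(x$locus_id) else {
    if (is.character(loci)) {
      missing <- setdiff(loci, x$locus_id)
      if (length(missing))
        aim_stop("unknown_locus", "unknown locus id(s): %s",
                 paste(missing, collapse = ", "))
      match(loci, x$locus_id)
    } else seq_along(x$locus_id)[loci]
  }
  if (!is.null(drop_loci))
    li <- li[!(x$locus_id[li] %in% drop_loci)]
  si <- if (is.null(samples)) seq_along(x$sample_id) else {
    if (is.character(samples)) match(samples, x$sample_id)
    else seq_along(x$sample_id)[samples]
  }
  genotype_table(x$dosage[si, li, drop = FALSE],
                 population = x$population[si],
                 sample_id = x$sample_id[si], locus_id = x$locus_id[li])
}

#' Relabel populations into broader groups
#'
#' Maps fine population labels (e.g. 1000-Genomes style codes) onto broader
#' groups (e.g. continental regions), pooling the individuals.  Labels not
#' named in `map` are kept unchanged.
#'
#' @param x a [genotype_table()].
#' @param map named character vector: `names(map)` are existing labels,
#'   values the group labels.
#' @return a `genotype_table` with the new labels.
#' @export
pool_populations <- function(x, map) {
  stopifnot(inherits(x, "genotype_table"))
  pop <- x$population
  hit <- pop %in% names(map)
  pop[hit] <- unname(map[pop[hit]])
  genotype_table(x$dosage, population = pop,
                 sample_id = x$sample_id, locus_id = x$locus_id)
}

#' Per-locus genotype counts
#'
#' Counts (n_II, n_ID, n_DD) of insertion homozygotes, heterozygotes and
#' deletion homozygotes per locus, optionally within one population.
#'
#' @param x a [genotype_table()].
#' @param population optional single label; `NULL` pools all samples.
#' @return integer matrix loci x 3 with columns `n_ii`, `n_id`, `n_dd`.
#' @export
locus_counts <- function(x, population = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  d <- x$dosage
  if (!is.null(population)) {
    keep <- x$population %in% population
    if (!any(keep))
      aim_stop("unknown_population", "no samples with label %s",
               paste(population, collapse = ", "))
    d <- d[keep, , drop = FALSE]
  }
  out <- cbind(n_ii = colSums(d == 2L, na.rm = TRUE),
               n_id = colSums(d == 1L, na.rm = TRUE),
               n_dd = colSums(d == 0L, na.rm = TRUE))
  rownames(out) <- x$locus_id
  out
}

#' Per-population insertion allele frequencies
#'
#' @param x a [genotype_table()].
#' @param loci optional locus subset.
#' @return numeric matrix populations x loci of insertion frequencies
#'   (NaN where a population has no observed genotypes at a locus).
#' @export
population_frequencies <- function(x, loci = NULL) {
  if (!is.null(loci)) x <- subset_table(x, loci = loci)
  pops <- sort(unique(x$population))
  out <- matrix(NA_real_, length(pops), length(x$locus_id),
                dimnames = list(pops, x$locus_id))
  for (p in pops) {
    cnt <- locus_counts(x, p)
    tot <- 2 * rowSums(cnt)
    out[p, ] <- (2 * cnt[, "n_ii"] + cnt[, "n_id"]) / tot
  }
  out
}
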