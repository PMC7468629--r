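#' Read a genotype TSV file
#'
#' The canonical exchange format is a tab-separated table with a header row
#' `sample`, `population`, then one column per locus.  Genotype cells may be
#' coded either as insertion dosages (`0`/`1`/`2`) or as allele pairs
#' (`II`, `ID`/`DI`, `DD`); `./.` (or an empty cell) marks a missing
#' genotype.  Both encodings may be mixed freely.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    aim_stop("empty_table", "genotype table %s has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 3L || tolower(header[1L]) != "sample" ||
      tolower(header[2L]) != "population")
    aim_stop("bad_header",
             "expected header 'sample<TAB>population<TAB><locus>...', got: %s",
             paste(utils::head(header, 4), collapse = " "))
  nc <- length(header)
  ragged <- which(vapply(cells[-1L], length, 1L) != nc)
  if (length(ragged))
    aim_stop("ragged_rows", "row(s) %s have a different number of fields than the header",
             paste(ragged + 1L, collapse = ", "))
  body <- do.call(rbind, cells[-1L])
  sample_id <- body[, 1L]
  population <- body[, 2L]
  raw <- body[, -(1:2), drop = FALSE]
  dosage <- apply(raw, c(1, 2), decode_genotype_cell)
  genotype_table(dosage, population = population, sample_id = sample_id,
                 locus_id = header[-(1:2)])
}

decode_genotype_cell <- function(cell) {
  s <- toupper(trimws(cell))
  if (s %in% c("./.", "", "NA")) return(NA_integer_)
  switch(s,
         "0" = 0L, "1" = 1L, "2" = 2L,
         "II" = 2L, "ID" = 1L, "DI" = 1L, "DD" = 0L,
         aim_stop("unknown_cell_token", "unknown genotype cell token '%s'", cell))
}

#' Write a genotype table as TSV
#'
#' Writes the dosage encoding (`0`/`1`/`2`, missing as `./.`); the written
#' file reads back into an identical table.
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  cells <- matrix(as.character(x$dosage), nrow = nrow(x$dosage))
  cells[is.na(cells)] <- "./."
  lines <- c(paste(c("sample", "population", x$locus_id), collapse = "\t"),
             vapply(seq_along(x$sample_id), function(i)
               paste(c(x$sample_id[i], x$population[i], cells[i, ]),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Import biallelic InDel genotypes from a VCF
#'
#' Convenience importer (the TSV format is canonical).  Keeps only biallelic
#' records whose REF and ALT alleles differ in length; multiallelic or
#' non-indel records are skipped and counted.  Dosage counts copies of the
#' designated insertion allele: by default the longer of REF/ALT.
#' Requires the `VariantAnnotation` package.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_population named character vector mapping VCF sample names
#'   to population labels.
#' @param insertion which allele counts as the insertion: `"longer"`
#'   (default), `"ref"`, or `"alt"`.
#' @param ignore_unmapped if `FALSE` (default) a VCF sample absent from
#'   `sample_population` is an error; if `TRUE` such samples are dropped.
#' @return a [genotype_table()] with attribute `skipped` (number of records
#'   skipped) and locus ids taken from the VCF ID column (or `chrom:pos`).
#' @export
read_vcf_biallelic_indels <- function(path, sample_population,
                                      insertion = c("longer", "ref", "alt"),
                                      ignore_unmapped = FALSE) {
  insertion <- match.arg(insertion)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    aim_stop("missing_dependency",
             "the VariantAnnotation package is required for VCF import")
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & !is.na(alt1) & nchar(ref) != nchar(alt1) &
    grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt1)
  skipped <- sum(!keep)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  ref <- ref[keep]; alt1 <- alt1[keep]
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(gt)))
  vcf_samples <- colnames(gt)
  unmapped <- setdiff(vcf_samples, names(sample_population))
  if (length(unmapped) && !ignore_unmapped)
    aim_stop("unmapped_sample", "VCF sample(s) not in population map: %s",
             paste(unmapped, collapse = ", "))
  use <- intersect(vcf_samples, names(sample_population))
  gt <- gt[, use, drop = FALSE]
  # which GT allele index (0=REF, 1=ALT) is the insertion allele
  ins_is_alt <- switch(insertion,
                       longer = nchar(alt1) > nchar(ref),
                       ref = rep(FALSE, length(ref)),
                       alt = rep(TRUE, length(ref)))
  alt_dose <- function(g) {
    # count ALT alleles in a diploid GT string; NA when missing
    if (g %in% c("./.", ".|.", ".")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1L]]
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }
  alt_counts <- apply(gt, c(1, 2), alt_dose)
  dosage <- ifelse(matrix(ins_is_alt, nrow(gt), ncol(gt)),
                   alt_counts, 2L - alt_counts)
  dosage <- t(dosage)                     # variants x samples -> samples x loci
  out <- genotype_table(dosage,
                        population = unname(sample_population[use]),
                        sample_id = use, locus_id = ids)
  attr(out, "skipped") <- skipped
  out
}

#' Export a genotype table in STRUCTURE two-row format
#'
#' One individual occupies two rows (one allele per row), one column per
#' locus; alleles are coded 1 (insertion) and 2 (deletion), missing as -9.
#' Heterozygotes are written insertion-first; the admixture likelihood is
#' invariant to within-genotype allele order so the convention is harmless.
#' Population labels become integer codes with a sidecar legend at
#' `<path>.pops`.
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  pops <- sort(unique(x$population))
  code <- match(x$population, pops)
  row_alleles <- function(dose, first) {
    # allele shown on this row: 1 = insertion, 2 = deletion, -9 missing
    out <- ifelse(is.na(dose), -9L,
                  ifelse(dose == 2L, 1L,
                         ifelse(dose == 0L, 2L, if (first) 1L else 2L)))
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$sample_id)) {
    d <- x$dosage[i, ]
    for (first in c(TRUE, FALSE)) {
      writeLines(paste(c(x$sample_id[i], code[i], row_alleles(d, first)),
                       collapse = " "), con)
    }
  }
  writeLines(paste(seq_along(pops), pops, sep = "\t"), paste0(path, ".pops"))
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' @param tree an `ape` `phylo` object (e.g. from [neighbor_joining()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a numeric matrix (or data frame) as CSV
#'
#' Thin wrapper used by the pipeline for all statistic tables; row names are
#' kept in a leading column.
#'
#' @param x matrix or data frame.
#' @param path output file path.
#' @param rowname_col header for the rowname column.
#' @return `path`, invisibly.
#' @export
write_stat_csv <- function(x, path, rowname_col = "id") {
  df <- as.data.frame(x)
  if (!is.null(rownames(x)) && !identical(rownames(x), as.character(seq_len(nrow(df))))) {
    df <- cbind(stats::setNames(data.frame(rownames(x)), rowname_col), df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
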