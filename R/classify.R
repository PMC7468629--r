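#' Train per-class allele frequencies for naive-Bayes assignment
#'
#' Per class (population or continental group) and locus, the smoothed
#' insertion frequency `(insertion count + s) / (2 n_obs + 2 s)` with
#' pseudo-count `s` per allele (Jeffreys-style default 0.5), guaranteeing
#' strictly interior frequencies and finite log-likelihoods.
#'
#' @param x a [genotype_table()]; its population labels are the classes.
#' @param smoothing pseudo-count `s` per allele (default 0.5; `s = 0`
#'   gives raw frequencies).
#' @return object of class `aim_training`: list with `classes`, `p`
#'   (classes x loci smoothed frequencies), `ins_count` and
#'   `allele_total` (raw per-class counts), `smoothing`, `locus_id`.
#' @export
train_frequencies <- function(x, smoothing = 0.5) {
  stopifnot(inherits(x, "genotype_table"), smoothing >= 0)
  classes <- sort(unique(x$population))
  empty <- setdiff(classes, x$population)
  if (length(empty))
    aim_stop("empty_class", "class with no individuals: %s", empty[1L])
  L <- length(x$locus_id)
  ins <- tot <- matrix(0, length(classes), L,
                       dimnames = list(classes, x$locus_id))
  for (cl in classes) {
    d <- x$dosage[x$population == cl, , drop = FALSE]
    ins[cl, ] <- colSums(d, na.rm = TRUE)
    tot[cl, ] <- 2 * colSums(!is.na(d))
  }
  p <- (ins + smoothing) / (tot + 2 * smoothing)
  structure(list(classes = classes, p = p, ins_count = ins,
                 allele_total = tot, smoothing = smoothing,
                 locus_id = x$locus_id),
            class = "aim_training")
}

# genotype log-likelihood matrix: samples x classes, HWE genotype
# probabilities at the class frequencies, missing loci skipped.
loglik_matrix <- function(dosage, training) {
  p <- training$p                       # classes x loci
  lp <- log(p); lq <- log(1 - p)
  d <- dosage
  obs <- !is.na(d)
  if (!any(obs)) aim_stop("no_usable_loci", "no usable (non-missing, trained) loci")
  d0 <- ifelse(obs, d, 0)
  # per copy: dose * log p + (2 - dose) * log q; heterozygote adds log 2
  ll <- d0 %*% t(lp) + ((2 - d0) * obs) %*% t(lq) +
    matrix(rowSums(d0 == 1 & obs) * log(2), nrow(d), nrow(p))
  colnames(ll) <- training$classes
  rownames(ll) <- rownames(dosage)
  ll
}

#' Classify individuals by naive-Bayes population assignment
#'
#' Per-class log-likelihood is the sum over non-missing loci of the log
#' Hardy-Weinberg genotype probability (`p^2`, `2pq`, `q^2`) at the class
#' frequencies; equal class priors; ties broken toward the
#' lexicographically smallest class label.
#'
#' @param x a [genotype_table()] (labels ignored) or a dosage matrix.
#' @param training an `aim_training` from [train_frequencies()].
#' @return data frame with `sample`, `assigned`, per-class posterior
#'   columns; attribute `loglik` holds the samples x classes
#'   log-likelihood matrix.
#' @export
classify <- function(x, training) {
  dosage <- if (inherits(x, "genotype_table")) x$dosage else as.matrix(x)
  common <- intersect(colnames(dosage), training$locus_id)
  if (length(common) == 0L)
    aim_stop("no_usable_loci", "no trained loci present in the query data")
  if (any(rowSums(!is.na(dosage[, common, drop = FALSE])) == 0L))
    aim_stop("no_usable_loci", "individual(s) with no non-missing trained loci")
  ll <- loglik_matrix(dosage[, common, drop = FALSE],
                      structure(list(classes = training$classes,
                                     p = training$p[, common, drop = FALSE]),
                                class = "aim_training"))
  post <- exp(ll - apply(ll, 1L, max))
  post <- post / rowSums(post)
  assigned <- training$classes[apply(ll, 1L, which.max)]  # classes sorted
  out <- data.frame(sample = rownames(dosage) %||% seq_len(nrow(dosage)),
                    assigned = assigned, post, row.names = NULL,
                    check.names = FALSE)
  attr(out, "loglik") <- ll
  out
}

#' Leave-one-out cross-validated population assignment
#'
#' For every individual, its alleles are removed from its own class's
#' training counts, class frequencies are re-smoothed, and the individual
#' is reassigned; results are aggregated into a confusion matrix of origin
#' (rows) by assigned class (columns).
#'
#' @param x a [genotype_table()]; every class must have at least 2
#'   individuals.
#' @param smoothing pseudo-count per allele, as in [train_frequencies()].
#' @return object of class `aim_confusion`: list with `counts`,
#'   `proportions` (rows summing to 1) and `classes`.
#' @export
loocv <- function(x, smoothing = 0.5) {
  stopifnot(inherits(x, "genotype_table"))
  sizes <- table(x$population)
  if (any(sizes < 2L))
    aim_stop("class_too_small", "class(es) with fewer than 2 individuals: %s",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
  training <- train_frequencies(x, smoothing)
  classes <- training$classes
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(origin = classes, assigned = classes))
  s <- training$smoothing
  for (i in seq_along(x$sample_id)) {
    cl <- x$population[i]
    d <- x$dosage[i, ]
    obs <- !is.na(d)
    ins <- training$ins_count
    tot <- training$allele_total
    ins[cl, obs] <- ins[cl, obs] - d[obs]
    tot[cl, obs] <- tot[cl, obs] - 2L
    p <- (ins + s) / (tot + 2 * s)
    tr_i <- structure(list(classes = classes, p = p, locus_id = x$locus_id),
                      class = "aim_training")
    res <- classify(x$dosage[i, , drop = FALSE], tr_i)
    counts[cl, res$assigned] <- counts[cl, res$assigned] + 1L
  }
  structure(list(counts = counts, proportions = counts / rowSums(counts),
                 classes = classes),
            class = "aim_confusion")
}

#' @export
print.aim_confusion <- function(x, ...) {
  cat("leave-one-out confusion matrix (row %):\n")
  print(round(100 * x$proportions, 2))
  invisible(x)
}

#' Per-class success ratios (confusion-matrix diagonal)
#'
#' @param confusion an `aim_confusion` from [loocv()], or a proportion
#'   matrix with rows summing to 1, or a raw count matrix.
#' @return named numeric vector of diagonal proportions.
#' @export
success_ratios <- function(confusion) {
  m <- if (inherits(confusion, "aim_confusion")) confusion$proportions
       else as.matrix(confusion)
  if (any(abs(rowSums(m) - 1) > 1e-9)) m <- m / rowSums(m)
  diag(m)
}
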