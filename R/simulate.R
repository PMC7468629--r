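#' Simulation configuration
#'
#' Describes a synthetic world of divergent continental groups under the
#' Balding-Nichols model plus optional admixed groups with fixed ancestry
#' proportions.  Per locus an ancestral insertion frequency `p0` is drawn
#' uniformly in `freq_range`; each source group draws its own frequency
#' from `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` so that `F` is the expected
#' divergence (F_st) from the ancestral pool; genotypes are binomial.
#' Admixed individuals draw the source of each of their two allele copies
#' independently from their Q vector, matching the admixture likelihood
#' fitted by [fit_admixture()].
#'
#' @param L number of unlinked biallelic loci.
#' @param groups named list: each element `list(n = , F = )` with group
#'   size and Balding-Nichols divergence `F` strictly in (0, 1).
#' @param admixed named list: each element `list(n = , Q = )` with `Q` a
#'   vector over the source groups (simplex), in the order of `groups`.
#' @param freq_range ancestral frequency bounds inside (0, 1); the default
#'   (0.1, 0.9) keeps loci informative, mimicking an AIM panel's
#'   ascertainment.
#' @param missing_rate genotype missingness applied uniformly at random.
#' @param seed integer RNG seed; the same config regenerates bit-identical
#'   data.
#' @return validated list of class `aim_simconfig`.
#' @export
sim_config <- function(L, groups, admixed = list(), freq_range = c(0.1, 0.9),
                       missing_rate = 0, seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    aim_stop("bad_config", "groups must be a named list")
  for (g in groups)
    if (!is.numeric(g$F) || g$F <= 0 || g$F >= 1 || g$n < 1)
      aim_stop("bad_config", "each group needs n >= 1 and F strictly in (0,1)")
  for (nm in names(admixed)) {
    q <- admixed[[nm]]$Q
    if (length(q) != length(groups) || any(q < 0) || abs(sum(q) - 1) > 1e-9)
      aim_stop("bad_config",
               "admixed group '%s' needs a Q vector on the simplex over the %d source groups",
               nm, length(groups))
  }
  if (length(freq_range) != 2L || freq_range[1L] >= freq_range[2L] ||
      freq_range[1L] <= 0 || freq_range[2L] >= 1)
    aim_stop("bad_config", "freq_range must satisfy 0 < lo < hi < 1")
  if (missing_rate < 0 || missing_rate >= 1)
    aim_stop("bad_config", "missing_rate must be in [0, 1)")
  structure(list(L = as.integer(L), groups = groups, admixed = admixed,
                 freq_range = freq_range, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "aim_simconfig")
}

#' Simulate a genotype dataset from a configuration
#'
#' @param config an [sim_config()].
#' @return object of class `aim_simdata`: list with `table` (a
#'   [genotype_table()]), `ancestral_freq` (length L), `group_freq`
#'   (source groups x L), `true_Q` (individuals x source groups, for every
#'   individual: point mass for source-group members), and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "aim_simconfig"))
  set.seed(config$seed)
  L <- config$L
  gnames <- names(config$groups)
  K <- length(gnames)
  p0 <- runif(L, config$freq_range[1L], config$freq_range[2L])
  gf <- matrix(NA_real_, K, L, dimnames = list(gnames, sprintf("L%03d", seq_len(L))))
  for (k in seq_len(K)) {
    F <- config$groups[[k]]$F
    shape <- (1 - F) / F
    gf[k, ] <- stats::rbeta(L, p0 * shape, (1 - p0) * shape)
  }
  all_labels <- c(gnames, names(config$admixed))
  dosage_rows <- list()
  pop <- character(0)
  trueQ <- NULL
  for (k in seq_len(K)) {
    n <- config$groups[[k]]$n
    d <- matrix(rbinom(n * L, 2L, rep(gf[k, ], each = n)), n, L)
    dosage_rows[[length(dosage_rows) + 1L]] <- d
    pop <- c(pop, rep(gnames[k], n))
    q <- matrix(0, n, K); q[, k] <- 1
    trueQ <- rbind(trueQ, q)
  }
  for (nm in names(config$admixed)) {
    spec <- config$admixed[[nm]]
    n <- spec$n
    d <- matrix(0L, n, L)
    for (copy in 1:2) {
      # per-copy source draw from Q (same Q for all members of the group)
      src <- matrix(sample.int(K, n * L, replace = TRUE, prob = spec$Q), n, L)
      pk <- matrix(gf[cbind(as.vector(src), rep(seq_len(L), each = n))], n, L)
      d <- d + matrix(rbinom(n * L, 1L, pk), n, L)
    }
    dosage_rows[[length(dosage_rows) + 1L]] <- d
    pop <- c(pop, rep(nm, n))
    trueQ <- rbind(trueQ, matrix(spec$Q, n, K, byrow = TRUE))
  }
  dosage <- do.call(rbind, dosage_rows)
  if (config$missing_rate > 0) {
    miss <- runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA_integer_
  }
  colnames(dosage) <- colnames(gf)
  rownames(dosage) <- sprintf("I%05d", seq_len(nrow(dosage)))
  colnames(trueQ) <- gnames
  rownames(trueQ) <- rownames(dosage)
  tab <- genotype_table(dosage, population = pop)
  structure(list(table = tab, ancestral_freq = p0, group_freq = gf,
                 true_Q = trueQ, config = config),
            class = "aim_simdata")
}

#' The standard synthetic world fixture
#'
#' Five continental-style reference groups under Balding-Nichols
#' divergence (AFR-like F = 0.20, EUR-like F = 0.12, EAS-like F = 0.15,
#' SAS-like F = 0.10, and an admixed AMR-like group with ancestry
#' (0.10, 0.45, 0.05, 0.40) over AFR/EUR/EAS/SAS) plus one admixed target
#' group with ancestry (0.03, 0.08, 0.89, 0.00) -- the structure of a
#' predominantly East Asian study group.  38 loci, 100 individuals per
#' group, fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param n_per_group group size (default 100).
#' @param L locus count (default 38).
#' @return an `aim_simdata`; the target group is labelled `"TARGET"`.
#' @export
make_world_fixture <- function(seed = 1L, n_per_group = 100L, L = 38L) {
  cfg <- sim_config(
    L = L,
    groups = list(
      "AFR-like" = list(n = n_per_group, F = 0.20),
      "EUR-like" = list(n = n_per_group, F = 0.12),
      "EAS-like" = list(n = n_per_group, F = 0.15),
      "SAS-like" = list(n = n_per_group, F = 0.10)),
    admixed = list(
      "AMR-like" = list(n = n_per_group, Q = c(0.10, 0.45, 0.05, 0.40)),
      "TARGET"   = list(n = n_per_group, Q = c(0.03, 0.08, 0.89, 0.00))),
    seed = seed)
  simulate_panel(cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the genotype TSV plus a JSON truth sidecar (true Q, group and
#' ancestral frequencies, config echo, seed).
#'
#' @param sim an `aim_simdata`.
#' @param path genotype TSV path; the sidecar goes to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(sim, path) {
  stopifnot(inherits(sim, "aim_simdata"))
  write_genotype_table(sim$table, path)
  truth <- list(seed = sim$config$seed,
                config = unclass(sim$config),
                ancestral_freq = sim$ancestral_freq,
                group_freq = sim$group_freq,
                true_Q = sim$true_Q)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
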