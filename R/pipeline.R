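#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param exclude_loci locus ids dropped from all cross-population stages
#'   (the forensic stage keeps the full panel, mirroring the situation
#'   where a locus lacks reference-population data).
#' @param target_group population label playing the study-group role: it
#'   is excluded from classifier training and from the reference
#'   frequencies of the supervised admixture stage, but kept in
#'   ordination.  `NULL` disables the supervised stage.
#' @param group_map optional named vector pooling fine population labels
#'   into continental groups for the group-level stages (F_st table,
#'   informativeness, LOOCV); `NULL` uses the labels as-is.
#' @param k_values K range for the admixture series.
#' @param restarts EM restarts per K.
#' @param smoothing classifier pseudo-count.
#' @param fst_threshold cutoff for the locus-exceedance counts.
#' @param seed root seed; each stochastic stage derives its own seed from
#'   it so stages are individually reproducible.
#' @param stages character vector selecting stages; any subset of
#'   `c("forensic", "informativeness", "fst", "classify", "admixture",
#'   "supervised", "ordination", "tree")`.
#' @return validated list of class `aim_runconfig`.
#' @export
run_config <- function(out_dir, exclude_loci = character(0),
                       target_group = NULL, group_map = NULL,
                       k_values = 2:5, restarts = 5L, smoothing = 0.5,
                       fst_threshold = 0.25, seed = 1L,
                       stages = c("forensic", "informativeness", "fst",
                                  "classify", "admixture", "supervised",
                                  "ordination", "tree")) {
  known <- c("forensic", "informativeness", "fst", "classify", "admixture",
             "supervised", "ordination", "tree")
  bad <- setdiff(stages, known)
  if (length(bad))
    aim_stop("bad_config", "unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, exclude_loci = exclude_loci,
                 target_group = target_group, group_map = group_map,
                 k_values = as.integer(k_values), restarts = as.integer(restarts),
                 smoothing = smoothing, fst_threshold = fst_threshold,
                 seed = as.integer(seed), stages = stages),
            class = "aim_runconfig")
}

#' Run the full panel-evaluation pipeline
#'
#' Executes, in order: forensic table + HWE/Bonferroni; Rosenberg
#' informativeness; locus-wise and population-pairwise Weir-Cockerham
#' F_st with threshold counts; leave-one-out naive-Bayes classification;
#' the admixture series over a K range with Evanno delta-K; supervised
#' ancestry components for the designated target group; PCA, MDS, and the
#' Nei D_A neighbor-joining tree.  Every stage writes a CSV (or Newick)
#' artifact into `config$out_dir` and is recorded in a JSON manifest;
#' identical seed and input reproduce byte-identical tables.
#'
#' @param x a [genotype_table()] or path to a genotype TSV.
#' @param config an [run_config()].
#' @return the manifest: list with `artifacts` (named paths), `seed`,
#'   `version`, `config` echo, `timings` (seconds per stage), and
#'   `settings` (design-decision defaults in effect).  Also written to
#'   `manifest.json`.
#' @export
run_all <- function(x, config) {
  stopifnot(inherits(config, "aim_runconfig"))
  if (is.character(x)) x <- read_genotype_table(x)
  stopifnot(inherits(x, "genotype_table"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- list()
  timings <- list()
  log_lines <- c(sprintf("aimpanel %s; root seed %d",
                         as.character(utils::packageVersion("aimpanel")),
                         config$seed),
                 sprintf("excluded loci: %s",
                         if (length(config$exclude_loci))
                           paste(config$exclude_loci, collapse = ", ") else "none"),
                 sprintf("settings: smoothing=%g, fst=Weir-Cockerham theta, mds=classical (Torgerson), em_restarts=%d",
                         config$smoothing, config$restarts))
  stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      aim_stop("stage_failure", "stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_lines <<- c(log_lines, sprintf("stage %s: ok (%.3fs)", name, timings[[name]]))
    res
  }
  # cross-population view: loci after exclusion, optionally pooled labels
  cross <- subset_table(x, drop_loci = config$exclude_loci)
  grouped <- if (is.null(config$group_map)) cross
             else pool_populations(cross, config$group_map)
  refs <- if (is.null(config$target_group)) grouped
          else subset_table(grouped, samples = grouped$population != config$target_group)

  stage("forensic", function() {
    ft <- forensic_table(x)
    pvals <- as.numeric(ft$P[ft$locus != "Mean"])
    bc <- bonferroni_correct(pvals)
    hwe <- data.frame(locus = ft$locus[ft$locus != "Mean"], P = pvals,
                      alpha_adjusted = bc$alpha_adjusted,
                      significant = bc$significant)
    artifacts$forensic_table <<- write_stat_csv(ft, out("forensic_table.csv"))
    artifacts$hwe_flags <<- write_stat_csv(hwe, out("hwe_flags.csv"))
  })
  stage("informativeness", function() {
    artifacts$informativeness <<-
      write_stat_csv(informativeness_table(refs), out("informativeness.csv"))
  })
  stage("fst", function() {
    lf <- locus_fst_table(refs)
    artifacts$locus_fst <<- write_stat_csv(lf, out("locus_fst.csv"), "locus")
    cnt <- count_loci_above(lf, config$fst_threshold)
    artifacts$fst_exceedance <<-
      write_stat_csv(data.frame(pair = names(cnt), count = as.integer(cnt)),
                     out("fst_exceedance.csv"))
    pf <- pairwise_fst_matrix(cross)
    artifacts$pairwise_fst <<-
      write_stat_csv(pf, out("pairwise_fst.csv"), "population")
  })
  stage("classify", function() {
    conf <- loocv(refs, smoothing = config$smoothing)
    pct <- round(100 * conf$proportions, 2)
    artifacts$confusion <<- write_stat_csv(pct, out("confusion.csv"), "origin")
  })
  stage("admixture", function() {
    series <- admixture_series(grouped, k_values = config$k_values,
                               restarts = config$restarts,
                               seed = config$seed + 100L)
    artifacts$admixture_loglik <<-
      write_stat_csv(series$loglik, out("admixture_loglik.csv"), "restart")
    if (length(series$k_values) >= 3L) {
      dk <- evanno_delta_k(series)
      artifacts$delta_k <<-
        write_stat_csv(data.frame(K = names(dk), delta_k = dk), out("delta_k.csv"))
    }
    best <- series$fits[[which.max(vapply(series$fits, function(f)
      f$log_likelihood, 0))]]
    qdf <- data.frame(sample = rownames(best$Q) %||% seq_len(nrow(best$Q)),
                      population = grouped$population, best$Q,
                      check.names = FALSE)
    artifacts$q_matrix <<- write_stat_csv(qdf, out("q_matrix.csv"))
    comp <- population_components(best, grouped$population)
    artifacts$population_components <<-
      write_stat_csv(comp, out("population_components.csv"), "population")
  })
  stage("supervised", function() {
    if (is.null(config$target_group)) return(invisible(NULL))
    ref_p <- population_frequencies(refs)
    tgt <- subset_table(grouped,
                        samples = grouped$population == config$target_group)
    Q <- fit_supervised_q(tgt, ref_p)
    artifacts$supervised_q <<- write_stat_csv(Q, out("supervised_q.csv"), "sample")
    artifacts$supervised_components <<-
      write_stat_csv(t(colMeans(Q)), out("supervised_components.csv"))
  })
  stage("ordination", function() {
    pca <- genotype_pca(grouped)
    sc <- data.frame(sample = rownames(pca$scores),
                     population = grouped$population,
                     pca$scores[, 1:min(4L, ncol(pca$scores)), drop = FALSE])
    artifacts$pca_scores <<- write_stat_csv(sc, out("pca_scores.csv"))
    fstm <- pairwise_fst_matrix(grouped)
    mds <- classical_mds(pmax(fstm, 0))
    artifacts$mds_coordinates <<-
      write_stat_csv(mds$coordinates, out("mds_coordinates.csv"), "population")
  })
  stage("tree", function() {
    dam <- da_matrix(grouped)
    artifacts$da_matrix <<- write_stat_csv(dam, out("da_matrix.csv"), "population")
    tree <- neighbor_joining(dam)
    artifacts$nj_tree <<- write_newick(tree, out("nj_tree.nwk"))
  })
  manifest <- list(artifacts = artifacts, seed = config$seed,
                   version = as.character(utils::packageVersion("aimpanel")),
                   config = unclass(config), timings = timings,
                   settings = list(smoothing = config$smoothing,
                                   fst_estimator = "weir_cockerham_theta",
                                   mds = "classical_torgerson",
                                   em_restarts = config$restarts))
  manifest_stable <- manifest
  manifest_stable$timings <- NULL   # timings vary run to run
  jsonlite::write_json(manifest_stable, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, out("run.log"))
  manifest
}
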