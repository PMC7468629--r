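test_that("EM log-likelihood is monotone and Q rows stay on the simplex", {
  cfg <- sim_config(L = 40, groups = list(A = list(n = 15, F = 0.2),
                                          B = list(n = 15, F = 0.2),
                                          C = list(n = 15, F = 0.2)),
                    missing_rate = 0.05, seed = 8)
  tab <- simulate_panel(cfg)$table
  for (K in 2:3) {
    fit <- fit_admixture(tab, K, seed = K, restarts = 2L, max_iter = 200L)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-9)
    expect_true(all(fit$Q >= 0))
    expect_true(all(fit$P > 0 & fit$P < 1))
  }
})

test_that("separable two-population case is recovered at K = 2", {
  g <- fixed_opposite_table(n_per = 15L, L = 20L)
  fit <- fit_admixture(g, 2, seed = 1, restarts = 3L)
  # up to label switching, Q rows approach the vertices
  main <- apply(fit$Q, 1, max)
  expect_true(all(main > 0.99))
  lab <- apply(fit$Q, 1, which.max)
  expect_equal(length(unique(lab[1:15])), 1L)
  expect_true(lab[1] != lab[16])
  # analytic maximum: every allele copy explained with probability ~1
  expect_gt(fit$log_likelihood, -1e-3 * 30 * 20)
})

test_that("K = 1 closed form: pooled frequencies and binomial log-likelihood", {
  set.seed(6)
  d <- matrix(rbinom(200, 2, 0.3), 20, 10,
              dimnames = list(sprintf("i%02d", 1:20), sprintf("L%02d", 1:10)))
  tab <- genotype_table(d, population = rep("P", 20))
  fit <- fit_admixture(tab, 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 20))
  p_hat <- pmin(pmax(colMeans(d) / 2, 1e-6), 1 - 1e-6)
  expect_equal(unname(fit$P[1, ]), unname(p_hat))
  ll <- sum(d * log(rep(p_hat, each = 20)) + (2 - d) * log(rep(1 - p_hat, each = 20)))
  expect_equal(fit$log_likelihood, ll)
  expect_error(fit_admixture(tab, 21), class = "aimpanel_bad_k")
})

test_that("supervised Q: analytic cases and parameter recovery at L = 500", {
  P <- rbind(A = rep(0.999, 10), B = rep(0.001, 10))
  colnames(P) <- paste0("L", 1:10)
  het <- matrix(1L, 1, 10, dimnames = list("x", paste0("L", 1:10)))
  expect_equal(unname(fit_supervised_q(het, P)[1, ]), c(0.5, 0.5),
               tolerance = 1e-6)
  hom <- matrix(2L, 1, 10, dimnames = list("x", paste0("L", 1:10)))
  expect_gt(fit_supervised_q(hom, P)[1, "A"], 0.99)
  # individuals simulated with Q = (0.89, 0.08, 0.03) over 3 sources at
  # L = 500 well-differentiated loci are recovered within +-0.05
  cfg <- sim_config(L = 500,
                    groups = list(EAS = list(n = 50, F = 0.15),
                                  EUR = list(n = 50, F = 0.12),
                                  AFR = list(n = 50, F = 0.20)),
                    admixed = list(STUDY = list(n = 50, Q = c(0.89, 0.08, 0.03))),
                    seed = 77)
  sim <- simulate_panel(cfg)
  tgt <- subset_table(sim$table, samples = sim$table$population == "STUDY")
  Q <- fit_supervised_q(tgt, sim$group_freq)
  expect_lt(max(abs(colMeans(Q) - c(0.89, 0.08, 0.03))), 0.05)
})

test_that("supervised fit with the true P beats the unsupervised fit", {
  cfg <- sim_config(L = 100,
                    groups = list(A = list(n = 40, F = 0.25),
                                  B = list(n = 40, F = 0.25)),
                    admixed = list(M = list(n = 40, Q = c(0.7, 0.3))),
                    seed = 55)
  sim <- simulate_panel(cfg)
  sup <- fit_supervised_q(sim$table, sim$group_freq)
  uns <- fit_admixture(sim$table, 2, seed = 2, restarts = 3L)
  # align unsupervised clusters to the true sources before comparing
  ref <- structure(list(P = sim$group_freq), class = "aim_admixture")
  uns <- align_clusters(uns, ref)
  err_sup <- mean(abs(sup - sim$true_Q))
  err_uns <- mean(abs(uns$Q - sim$true_Q))
  expect_lte(err_sup, err_uns + 1e-8)
})

test_that("unsupervised parameter recovery on model-generated data (K = 3)", {
  cfg <- sim_config(L = 300,
                    groups = list(A = list(n = 100, F = 0.25),
                                  B = list(n = 100, F = 0.25),
                                  C = list(n = 100, F = 0.25)),
                    seed = 99)
  sim <- simulate_panel(cfg)
  fit <- fit_admixture(sim$table, 3, seed = 4, restarts = 3L, max_iter = 300L)
  ref <- structure(list(P = sim$group_freq), class = "aim_admixture")
  fit <- align_clusters(fit, ref)
  expect_lt(mean(abs(fit$Q - sim$true_Q)), 0.05)
})

test_that("population components average Q per label on the simplex", {
  Q <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1), c(0.2, 0.8))
  comp <- population_components(Q, c("X", "X", "Y", "Y"))
  expect_equal(unname(comp["X", ]), c(0.75, 0.25))
  expect_equal(unname(comp["Y", ]), c(0.1, 0.9))
  expect_equal(unname(rowSums(comp)), c(1, 1))
  # all rows identical -> mean equals that row
  same <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  expect_equal(unname(population_components(same, rep("Z", 4))["Z", ]),
               c(0.3, 0.7))
})

test_that("Evanno delta-K: hand-worked example, linear case, degeneracies", {
  # L exactly linear in K -> zero second difference everywhere
  lin <- matrix(rep(c(-40, -30, -20, -10), each = 4), 4, 4)
  lin <- lin + matrix(rnorm(16, sd = 0), 4, 4)  # deterministic
  lin_j <- sweep(lin, 1, c(0, 0.1, -0.1, 0.05), "+")  # restart jitter, same per K
  dk <- evanno_delta_k(lin_j, k_values = 1:4)
  expect_equal(unname(dk), c(0, 0), tolerance = 1e-9)
  # hand example: means (-100, -50, -45, -44), sd 1 per K
  dk2 <- evanno_delta_k(c(-100, -50, -45, -44), k_values = 1:4, sd = 1)
  expect_equal(unname(dk2["K2"]), 45)
  expect_equal(unname(dk2["K3"]), abs(-44 - 2 * (-45) + (-50)))
  # scale invariance: scaling L and sd together leaves delta-K unchanged
  dk3 <- evanno_delta_k(10 * c(-100, -50, -45, -44), k_values = 1:4, sd = 10)
  expect_equal(dk3, dk2)
  # zero sd is a named degenerate error, not infinity
  expect_error(evanno_delta_k(matrix(rep(c(-3, -2, -1), each = 3), 3, 3)),
               class = "aimpanel_degenerate_sd")
  expect_error(evanno_delta_k(c(-3, -2, -1)), class = "aimpanel_missing_sd")
})

test_that("admixture series produces aligned fits and a delta-K table", {
  sim <- make_world_fixture(seed = 21, n_per_group = 25L)
  series <- admixture_series(sim$table, k_values = 2:4, restarts = 3L,
                             seed = 11, max_iter = 150L)
  expect_equal(dim(series$loglik), c(3L, 3L))
  expect_true(all(is.finite(series$loglik)))
  dk <- evanno_delta_k(series)
  expect_named(dk, "K3")
  expect_gte(dk[["K3"]], 0)
})
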