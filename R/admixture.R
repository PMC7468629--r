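#' Maximum-likelihood admixture fit at fixed K
#'
#' Fits the standard admixture model (each individual a mixture over K
#' clusters with proportions Q, each cluster with its own insertion
#' frequencies P) by EM, maximising the binomial log-likelihood
#' `sum_{i,l} [ g log(QP) + (2 - g) log(Q(1-P)) ]` per allele copy.  This
#' is the same likelihood STRUCTURE's admixture model samples from, fitted
#' as a point estimate (as the ADMIXTURE program does), which is what
#' stacked-bar ancestry summaries report.  Multiple seeded restarts are
#' run and the best log-likelihood kept.
#'
#' @param x a [genotype_table()] or dosage matrix.
#' @param K number of clusters (>= 1; K = 1 is the closed-form pooled fit,
#'   allowed so delta-K series can include it).
#' @param seed integer seed for the restart initialisations.
#' @param restarts independent random restarts (default 10).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return object of class `aim_admixture`: list with `K`, `Q`
#'   (individuals x K, rows on the simplex), `P` (K x loci insertion
#'   frequencies, clipped to (1e-6, 1-1e-6)), `log_likelihood`,
#'   `loglik_trace` of the best restart, `iterations`, `converged`,
#'   `seed`, `restart_logliks`.
#' @export
fit_admixture <- function(x, K, seed = 1L, restarts = 10L,
                          max_iter = 500L, tol = 1e-6) {
  G <- if (inherits(x, "genotype_table")) x$dosage else as.matrix(x)
  n <- nrow(G)
  if (K > n)
    aim_stop("bad_k", "K = %d exceeds the number of individuals (%d)", K, n)
  if (K < 1L) aim_stop("bad_k", "K must be >= 1")
  obs <- !is.na(G)
  G0 <- ifelse(obs, G, 0)
  if (K == 1L) {
    p <- clip_p(colSums(G0) / (2 * colSums(obs)))
    ll <- sum(G0 * log(rep(p, each = n)) +
                ((2 - G0) * obs) * log(rep(1 - p, each = n)))
    return(structure(list(K = 1L, Q = matrix(1, n, 1,
                                             dimnames = list(rownames(G), "C1")),
                          P = matrix(p, 1L, ncol(G),
                                     dimnames = list("C1", colnames(G))),
                          log_likelihood = ll, loglik_trace = ll,
                          iterations = 0L, converged = TRUE, seed = seed,
                          restart_logliks = ll),
                     class = "aim_admixture"))
  }
  best <- NULL
  rl <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    fit <- admixture_em_once(G0, obs, K, max_iter, tol)
    rl[r] <- fit$log_likelihood
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  dimnames(best$Q) <- list(rownames(G), paste0("C", seq_len(K)))
  dimnames(best$P) <- list(paste0("C", seq_len(K)), colnames(G))
  structure(c(best, list(K = K, seed = seed, restart_logliks = rl)),
            class = "aim_admixture")
}

clip_p <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

admixture_em_once <- function(G0, obs, K, max_iter, tol) {
  n <- nrow(G0); L <- ncol(G0)
  Q <- matrix(rgamma_dirichlet(n, K), n, K)
  P <- matrix(runif(K * L, 0.05, 0.95), K, L)
  Gc <- (2 - G0) * obs                       # deletion copies, 0 at missing
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- Q %*% P                             # mixture insertion prob
    B <- Q %*% (1 - P)
    ll <- sum(G0 * log_at_obs(A, obs) + Gc * log_at_obs(B, obs))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    WA <- ifelse(obs, G0 / A, 0)             # weights per insertion copy
    WB <- ifelse(obs, Gc / B, 0)
    # Q update: responsibilities summed over loci and both copy types
    R <- Q * (WA %*% t(P) + WB %*% t(1 - P))
    Q <- R / rowSums(R)
    # P update
    num <- P * (t(Q) %*% WA)
    den <- num + (1 - P) * (t(Q) %*% WB)
    P <- clip_p(ifelse(den > 0, num / den, P))
  }
  list(Q = Q, P = P, log_likelihood = trace[length(trace)],
       loglik_trace = trace, iterations = it, converged = converged)
}

log_at_obs <- function(M, obs) {
  out <- matrix(0, nrow(M), ncol(M))
  out[obs] <- log(M[obs])
  out
}

rgamma_dirichlet <- function(n, K, alpha = 1) {
  g <- matrix(stats::rgamma(n * K, alpha), n, K)
  g / rowSums(g)
}

#' Supervised ancestry proportions with fixed reference frequencies
#'
#' EM over Q only, holding per-cluster insertion frequencies fixed (e.g.
#' estimated from labelled reference populations).  The likelihood is
#' concave in each individual's Q row, so a uniform start converges to the
#' global maximum and no restarts are needed.
#'
#' @param x a [genotype_table()] or dosage matrix of the individuals to
#'   resolve.
#' @param reference_p clusters x loci matrix of insertion frequencies
#'   (rownames are the ancestry labels; columns must cover the loci of
#'   `x`).
#' @param max_iter,tol stopping rule as in [fit_admixture()].
#' @return individuals x clusters Q matrix, rows on the simplex.
#' @export
fit_supervised_q <- function(x, reference_p, max_iter = 2000L, tol = 1e-8) {
  G <- if (inherits(x, "genotype_table")) x$dosage else as.matrix(x)
  reference_p <- as.matrix(reference_p)
  common <- intersect(colnames(G), colnames(reference_p))
  if (length(common)) {
    G <- G[, common, drop = FALSE]
    reference_p <- reference_p[, common, drop = FALSE]
  }
  if (ncol(G) != ncol(reference_p))
    aim_stop("bad_reference", "reference frequencies do not cover the query loci")
  P <- clip_p(reference_p)
  K <- nrow(P); n <- nrow(G)
  obs <- !is.na(G)
  G0 <- ifelse(obs, G, 0)
  Gc <- (2 - G0) * obs
  Q <- matrix(1 / K, n, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    A <- Q %*% P
    B <- Q %*% (1 - P)
    ll <- sum(G0 * log_at_obs(A, obs) + Gc * log_at_obs(B, obs))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    WA <- ifelse(obs, G0 / A, 0)
    WB <- ifelse(obs, Gc / B, 0)
    R <- Q * (WA %*% t(P) + WB %*% t(1 - P))
    Q <- R / rowSums(R)
  }
  dimnames(Q) <- list(rownames(G), rownames(P))
  Q
}

#' Mean ancestry components per population label
#'
#' @param fit an `aim_admixture` fit, or a Q matrix.
#' @param labels population label per individual (row of Q).
#' @return matrix labels x K of mean Q vectors (each row on the simplex).
#' @export
population_components <- function(fit, labels) {
  Q <- if (inherits(fit, "aim_admixture")) fit$Q else as.matrix(fit)
  stopifnot(length(labels) == nrow(Q))
  groups <- sort(unique(labels))
  out <- t(vapply(groups, function(g)
    colMeans(Q[labels == g, , drop = FALSE]), numeric(ncol(Q))))
  rownames(out) <- groups
  out
}

#' Align cluster labels of one fit to a reference fit
#'
#' Greedy matching on the correlation of the cluster allele-frequency
#' vectors; used so stacked-bar output and tests are invariant to EM label
#' switching.
#'
#' @param fit an `aim_admixture` fit to permute.
#' @param reference an `aim_admixture` fit (same loci) whose cluster order
#'   is the target; may have a different K (extra clusters keep their
#'   order).
#' @return `fit` with columns of Q / rows of P permuted.
#' @export
align_clusters <- function(fit, reference) {
  P1 <- reference$P; P2 <- fit$P
  k1 <- nrow(P1); k2 <- nrow(P2)
  cors <- matrix(-Inf, k1, k2)
  for (i in seq_len(k1)) for (j in seq_len(k2))
    cors[i, j] <- stats::cor(P1[i, ], P2[j, ])
  cors[is.na(cors)] <- -Inf
  assigned <- rep(NA_integer_, k1)
  work <- cors
  for (step in seq_len(min(k1, k2))) {
    idx <- which(work == max(work), arr.ind = TRUE)[1, ]
    assigned[idx[1L]] <- idx[2L]
    work[idx[1L], ] <- -Inf
    work[, idx[2L]] <- -Inf
  }
  perm <- c(assigned[!is.na(assigned)], setdiff(seq_len(k2), assigned))
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$P <- fit$P[perm, , drop = FALSE]
  colnames(fit$Q) <- paste0("C", seq_len(k2))
  rownames(fit$P) <- paste0("C", seq_len(k2))
  fit
}

#' Run admixture fits across a range of K with restarts
#'
#' @param x a [genotype_table()] or dosage matrix.
#' @param k_values integer vector of K values (consecutive values make the
#'   delta-K statistic well-defined at interior K).
#' @param restarts restarts per K.
#' @param seed root seed; each (K, restart) gets a distinct derived seed.
#' @param ... passed to [fit_admixture()] (`max_iter`, `tol`).
#' @return object of class `aim_runseries`: list with `k_values`, `loglik`
#'   (restarts x K matrix), `fits` (best fit per K), `seed`.
#' @export
admixture_series <- function(x, k_values = 2:5, restarts = 10L, seed = 1L, ...) {
  k_values <- sort(unique(as.integer(k_values)))
  ll <- matrix(NA_real_, restarts, length(k_values),
               dimnames = list(NULL, paste0("K", k_values)))
  fits <- vector("list", length(k_values))
  for (ki in seq_along(k_values)) {
    K <- k_values[ki]
    best <- NULL
    for (r in seq_len(restarts)) {
      f <- fit_admixture(x, K, seed = seed + 1000L * ki + r, restarts = 1L, ...)
      ll[r, ki] <- f$log_likelihood
      if (is.null(best) || f$log_likelihood > best$log_likelihood) best <- f
    }
    fits[[ki]] <- best
  }
  structure(list(k_values = k_values, loglik = ll, fits = fits, seed = seed),
            class = "aim_runseries")
}

#' Evanno delta-K statistic
#'
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K))`,
#' the absolute second difference of the log-likelihood across K averaged
#' over restarts, scaled by the between-restart standard deviation
#' (Evanno et al. 2005).  Defined only at interior K values.
#'
#' @param loglik either an `aim_runseries`, a restarts x K matrix of
#'   log-likelihoods, or a numeric vector of mean log-likelihoods (in
#'   which case `sd` must be supplied).
#' @param k_values K value per column/entry; defaults to those stored in
#'   the series or to consecutive integers starting at the first column
#'   name (else 1).
#' @param sd per-K standard deviations, required when `loglik` is a plain
#'   vector of means.
#' @return named numeric vector of delta-K at interior K values.
#' @export
evanno_delta_k <- function(loglik, k_values = NULL, sd = NULL) {
  if (inherits(loglik, "aim_runseries")) {
    k_values <- loglik$k_values
    loglik <- loglik$loglik
  }
  if (is.matrix(loglik)) {
    if (is.null(k_values)) k_values <- seq_len(ncol(loglik))
    sds <- apply(loglik, 2L, stats::sd)
    second <- loglik[, -c(1L, ncol(loglik)), drop = FALSE]
    d2 <- abs(loglik[, -(1:2), drop = FALSE] - 2 * second +
                loglik[, seq_len(ncol(loglik) - 2L), drop = FALSE])
    num <- colMeans(d2)
  } else {
    if (is.null(sd))
      aim_stop("missing_sd", "per-K sd is required when loglik is a vector of means")
    if (is.null(k_values)) k_values <- seq_along(loglik)
    sds <- rep_len(sd, length(loglik))
    L <- length(loglik)
    num <- abs(loglik[-(1:2)] - 2 * loglik[-c(1L, L)] + loglik[seq_len(L - 2L)])
  }
  interior <- seq_along(k_values)[-c(1L, length(k_values))]
  s_int <- sds[interior]
  if (any(s_int == 0))
    aim_stop("degenerate_sd",
             "zero between-restart sd at K = %s; delta-K undefined",
             paste(k_values[interior][s_int == 0], collapse = ", "))
  stats::setNames(num / s_int, paste0("K", k_values[interior]))
}
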