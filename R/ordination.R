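#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per locus, columns are centred, and
#' (for `mode = "patterson"`) scaled by `sqrt(p(1-p))` with `p` the
#' insertion frequency, before a singular value decomposition.  Component
#' signs follow a deterministic convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param x a [genotype_table()] or dosage matrix (>= 2 samples).
#' @param mode `"center"` (covariance PCA, default) or `"patterson"`
#'   (frequency-standardised).
#' @param ncomp number of components to keep (default all).
#' @return object of class `aim_pca`: list with `scores` (samples x
#'   components), `loadings` (loci x components), `explained` (variance
#'   fractions, non-increasing), `mode`.
#' @export
genotype_pca <- function(x, mode = c("center", "patterson"), ncomp = NULL) {
  mode <- match.arg(mode)
  G <- if (inherits(x, "genotype_table")) x$dosage else as.matrix(x)
  if (nrow(G) < 2L)
    aim_stop("too_few_samples", "PCA needs at least 2 samples")
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  Z <- sweep(G, 2L, mu)
  if (mode == "patterson") {
    p <- mu / 2
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    Z <- sweep(Z, 2L, s, "/")
  }
  sv <- svd(Z)
  d <- sv$d
  k <- min(ncomp %||% length(d), length(d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(G), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained = d^2 / sum(d^2), mode = mode),
            class = "aim_pca")
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centres the squared distance matrix, takes the top eigenvectors
#' scaled by root eigenvalues, and reports Kruskal stress-1 of the
#' embedding together with any negative eigenvalues (non-Euclidean
#' residual) as diagnostics.  The configuration is centred at the origin
#' and defined up to rotation/reflection.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal (or
#'   a `dist`).
#' @param dims embedding dimension (default 2).
#' @return object of class `aim_mds`: list with `coordinates` (points x
#'   dims), `eigenvalues` (all), `stress` (Kruskal stress-1),
#'   `negative_eigenvalues`.
#' @export
classical_mds <- function(d, dims = 2L) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(diag(D) != 0) || any(D < 0))
    aim_stop("bad_distance_matrix",
             "need a symmetric non-negative matrix with zero diagonal")
  n <- nrow(D)
  if (dims >= n) aim_stop("bad_dims", "dims must be < number of points")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(dims)]
  if (any(lam <= 0))
    aim_stop("degenerate_embedding",
             "fewer than %d positive eigenvalues in the doubly-centred matrix", dims)
  coords <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Dim", seq_len(dims))
  emb <- as.matrix(stats::dist(coords))
  up <- upper.tri(D)
  stress <- sqrt(sum((D[up] - emb[up])^2) / sum(D[up]^2))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 stress = stress,
                 negative_eigenvalues = e$values[e$values < 0]),
            class = "aim_mds")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion and branch-length
#' formulas; ties in the Q criterion are broken deterministically toward
#' the lowest node-index pair.  The result is an unrooted tree returned as
#' an `ape` `phylo` object whose root node is the final trifurcation (the
#' NJ convention).  Negative branch lengths are kept unless clamped.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 leaves with
#'   labelled rows.
#' @param clamp_negative set negative branch lengths to zero.
#' @return an unrooted `phylo` tree with the input labels as tips.
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) aim_stop("too_few_leaves", "neighbor joining needs >= 3 leaves")
  if (!isSymmetric(unname(D), tol = 1e-8))
    aim_stop("bad_distance_matrix", "distance matrix must be symmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # nodes carry their subtree's Newick string; joins merge the strings
  active <- seq_len(n)
  next_id <- n
  newick <- as.list(labels)
  dm <- D
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    r <- length(active)
    sub <- dm[active, active, drop = FALSE]
    R <- rowSums(sub)
    Qc <- (r - 2) * sub - outer(R, R, "+")
    diag(Qc) <- Inf
    idx <- which(Qc == min(Qc), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
    i <- min(idx); j <- max(idx)
    dij <- sub[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dij - bi
    if (clamp_negative) { bi <- max(bi, 0); bj <- max(bj, 0) }
    ai <- active[i]; aj <- active[j]
    next_id <- next_id + 1L
    new_nw <- sprintf("(%s:%s,%s:%s)", newick[[ai]], fmt(bi),
                      newick[[aj]], fmt(bj))
    # grow matrices for the new node
    dnew <- (dm[ai, ] + dm[aj, ] - dij) / 2
    dm <- rbind(cbind(dm, dnew), c(dnew, 0))
    newick[[next_id]] <- new_nw
    active <- c(setdiff(active, c(ai, aj)), next_id)
  }
  # final trifurcation (three-point formulas)
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (dm[a, b] + dm[a, c3] - dm[b, c3]) / 2
  lb <- (dm[a, b] + dm[b, c3] - dm[a, c3]) / 2
  lc <- (dm[a, c3] + dm[b, c3] - dm[a, b]) / 2
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  nw <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[[a]], fmt(la),
                newick[[b]], fmt(lb), newick[[c3]], fmt(lc))
  ape::read.tree(text = nw)
}

#' Expand a tree into its additive (patristic) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' exact inverse of [neighbor_joining()] on additive inputs.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric matrix over the tip labels.
#' @export
tree_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
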