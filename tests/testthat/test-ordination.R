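test_that("PCA matches a direct SVD oracle and fixes signs deterministically", {
  set.seed(3)
  d <- matrix(rbinom(300, 2, 0.5), 30, 10,
              dimnames = list(sprintf("i%02d", 1:30), sprintf("L%02d", 1:10)))
  tab <- genotype_table(d, population = rep("P", 30))
  res <- genotype_pca(tab)
  Z <- sweep(d, 2, colMeans(d))
  sv <- svd(Z)
  oracle <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    expect_equal(abs(unname(res$scores[, j])), abs(oracle[, j]),
                 tolerance = 1e-8)
    # sign convention: dominant loading positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  expect_equal(unname(colMeans(res$scores)), rep(0, ncol(res$scores)),
               tolerance = 1e-10)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_equal(sum(res$explained), 1)
})

test_that("PCA separates fixed blocks and maps duplicates identically", {
  g <- fixed_opposite_table(n_per = 10L, L = 8L)
  # add tiny noise so the matrix is not exactly rank 1 degenerate
  res <- genotype_pca(g)
  expect_gt(res$explained[1], 0.99)
  expect_lt(max(res$scores[1:10, 1]) * min(res$scores[11:20, 1]), 0)
  # duplicated individual gets identical scores
  d2 <- rbind(g$dosage, dup = g$dosage[1, ])
  tab2 <- genotype_table(d2, population = c(g$population, "A"),
                         sample_id = c(g$sample_id, "dup"))
  res2 <- genotype_pca(tab2)
  expect_equal(unname(res2$scores["dup", ]), unname(res2$scores[1, ]))
  expect_error(genotype_pca(g$dosage[1, , drop = FALSE]),
               class = "aimpanel_too_few_samples")
})

test_that("PCA scores are sign-invariant under locus reordering", {
  set.seed(9)
  d <- matrix(rbinom(400, 2, runif(20, 0.2, 0.8)), 20, 20,
              dimnames = list(sprintf("i%02d", 1:20), sprintf("L%02d", 1:20)))
  tab <- genotype_table(d, population = rep("P", 20))
  perm <- sample(20)
  tab2 <- subset_table(tab, loci = tab$locus_id[perm])
  s1 <- genotype_pca(tab)$scores[, 1:3]
  s2 <- genotype_pca(tab2)$scores[, 1:3]
  for (j in 1:3) expect_equal(abs(s1[, j]), abs(s2[, j]), tolerance = 1e-8)
})

test_that("classical MDS embeds Euclidean inputs exactly", {
  set.seed(17)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:6)
  res <- classical_mds(D, dims = 2)
  expect_equal(as.matrix(dist(res$coordinates)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(unname(colMeans(res$coordinates)), c(0, 0), tolerance = 1e-10)
  expect_lt(res$stress, 1e-8)
  # agreement with the stats::cmdscale reference up to rotation/reflection
  ref <- stats::cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(res$coordinates)), as.matrix(dist(ref)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # three equidistant points form an equilateral triangle
  eq <- matrix(1, 3, 3) - diag(3)
  tri <- classical_mds(eq, dims = 2)$coordinates
  expect_equal(unname(as.matrix(dist(tri))), unname(eq), tolerance = 1e-8)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "aimpanel_bad_distance_matrix")
})

test_that("NJ: three-taxon closed form and agreement with the ape reference", {
  D <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["B", "C"] <- D["C", "B"] <- 8
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(2, 3, 5))
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    m <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
    ours <- neighbor_joining(m)
    ref <- ape::nj(m)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    expect_equal(tree_distances(ours)[rownames(m), rownames(m)],
                 tree_distances(ref)[rownames(m), rownames(m)],
                 tolerance = 1e-9)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)),
               class = "aimpanel_too_few_leaves")
})

test_that("NJ inverts tree-to-additive-distance expansion exactly", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    tree <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tree)
    rec <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(tree_distances(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  # ultrametric 4-taxon input recovers the generating topology
  ultra <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rec <- neighbor_joining(ape::cophenetic.phylo(ultra))
  expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(ultra)), 0,
               ignore_attr = TRUE)
})

test_that("admixed target individuals fall inside their sources' PC hull", {
  sim <- make_world_fixture(seed = 13)
  res <- genotype_pca(sim$table)
  sc <- res$scores[, 1:2]
  pop <- sim$table$population
  cent <- sapply(c("AFR-like", "EUR-like", "EAS-like", "SAS-like"), function(g)
    colMeans(sc[pop == g, ]))
  tgt_mean <- colMeans(sc[pop == "TARGET", ])
  # the target centroid lies within the bounding box of the source
  # centroids (a qualitative analog of clustering with its main source)
  expect_true(all(tgt_mean >= apply(cent, 1, min) - 1e-9))
  expect_true(all(tgt_mean <= apply(cent, 1, max) + 1e-9))
  # and it sits closest to its dominant (EAS-like) source
  dists <- sqrt(colSums((cent - tgt_mean)^2))
  expect_equal(names(which.min(dists)), "EAS-like")
})
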