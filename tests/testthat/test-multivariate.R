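test_that("correlation matrix matches a direct-summation oracle", {
  set.seed(14)
  m <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("x", "y", "z")))
  out <- correlation_matrix(m)
  # independent oracle: explicit covariance sums
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(out$r[i, j], pearson(m[, i], m[, j]), tolerance = 1e-12)
  }
  expect_equal(diag(out$r), c(x = 1, y = 1, z = 1))
  expect_equal(out$r, t(out$r))
  expect_equal(out$p, t(out$p))
})

test_that("duplicated and negated columns give r = 1 and r = -1", {
  set.seed(15)
  v <- rnorm(10)
  m <- cbind(a = v, b = v, c = -v)
  out <- correlation_matrix(m)
  expect_equal(out$r["a", "b"], 1, tolerance = 1e-12)
  expect_lt(out$p["a", "b"], 1e-10)
  expect_equal(out$r["a", "c"], -1, tolerance = 1e-12)
  expect_equal(unname(out$stars["a", "b"]), "***")
})

test_that("zero-variance columns are flagged undefined", {
  m <- cbind(a = rnorm(6), b = rep(2, 6))
  expect_warning(out <- correlation_matrix(m), "zero-variance")
  expect_true(all(is.na(out$r["b", ])))
  expect_true(all(is.na(out$r[, "b"])))
})

test_that("PCA eigenvalues match the eigendecomposition of the correlation matrix", {
  set.seed(16)
  for (i in 1:5) {
    m <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("e%d", 1:10),
                                                  sprintf("t%d", 1:6)))
    p <- trait_pca(m)
    oracle <- sort(eigen(cor(m), symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(unname(p$eigenvalues), oracle, tolerance = 1e-10)
    expect_equal(sum(p$contributions), 100, tolerance = 1e-10)
    expect_true(all(diff(p$contributions) <= 1e-12))
  }
})

test_that("PCA scores are the standardized data times the loadings", {
  set.seed(17)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("e%d", 1:8),
                                               sprintf("t%d", 1:5)))
  p <- trait_pca(m)
  z <- scale(m)
  expect_equal(unname(p$scores), unname(z %*% p$loadings), tolerance = 1e-10)
  # cross-products of scores are diagonal (components are orthogonal)
  g <- crossprod(p$scores)
  expect_equal(unname(g), diag(diag(g)), tolerance = 1e-8)
  # full reconstruction recovers the standardized matrix
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(z),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the sign convention makes repeated decompositions identical", {
  set.seed(18)
  m <- matrix(rnorm(50), 10, 5, dimnames = list(sprintf("e%d", 1:10),
                                                sprintf("t%d", 1:5)))
  p1 <- trait_pca(m); p2 <- trait_pca(m)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$loadings, p2$loadings)
  for (j in seq_len(ncol(p1$loadings))) {
    dom <- which.max(abs(p1$loadings[, j]))
    expect_gt(p1$loadings[dom, j], 0)
  }
})

test_that("a single varying column concentrates all variance in PC1", {
  m <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = rep(2, 4))
  rownames(m) <- sprintf("e%d", 1:4)
  expect_error(trait_pca(m), "zero-variance")          # cannot standardize
  p <- trait_pca(m, standardize = FALSE)
  expect_equal(p$contributions[1], 100, tolerance = 1e-10)
})

test_that("ranking value is the contribution-weighted score sum", {
  # rank-1 data: contribution vector is (100, 0, ...), so RV = 100 * PC1
  m <- cbind(a = c(1, 3, 2), b = c(2, 6, 4))
  rownames(m) <- c("x", "y", "z")
  p <- trait_pca(m, standardize = FALSE)
  rv <- ranking_values(p, n_components = 2)
  expect_equal(rv$ranking_value, 100 * rv$PC1, tolerance = 1e-8)

  # hand arithmetic on a 3-ecotype standardized PCA
  set.seed(19)
  m2 <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  p2 <- trait_pca(m2)
  rv2 <- ranking_values(p2, n_components = 3)
  manual <- p2$scores[, 1] * p2$contributions[1] +
    p2$scores[, 2] * p2$contributions[2] +
    p2$scores[, 3] * p2$contributions[3]
  expect_equal(rv2$ranking_value, unname(manual[rv2$ecotype]), tolerance = 1e-10)

  expect_error(ranking_values(p2, n_components = 9), "exceeds")
})

test_that("numerical ranks are a dense descending permutation with stable ties", {
  expect_equal(dense_rank_desc(c(3, 1, 2)), c(1L, 3L, 2L))
  expect_equal(dense_rank_desc(c(5, 5, 1), ids = c("b", "a", "c")),
               c(2L, 1L, 3L))
  set.seed(20)
  v <- rnorm(25)
  expect_setequal(dense_rank_desc(v), 1:25)
})

test_that("ranking is equivariant to relabeling of the rows", {
  set.seed(21)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("e%02d", 1:12), sprintf("t%d", 1:5)))
  rv <- ranking_values(trait_pca(m), n_components = 4)
  perm <- sample.int(12)
  rv_p <- ranking_values(trait_pca(m[perm, ]), n_components = 4)
  joined <- merge(rv, rv_p, by = "ecotype")
  expect_equal(joined$numerical_rank.x, joined$numerical_rank.y)
})

test_that("published ranking values sort into the published numerical ranks", {
  t4 <- load_fixture("table4")
  expect_equal(dense_rank_desc(t4$ranking_value, t4$ecotype), t4$rank)
  expect_equal(t4$ecotype[t4$rank == 1], "K17")
  expect_equal(t4$ecotype[t4$rank == 35], "K9")
})

test_that("identical rows merge at height zero; oracle matches average linkage", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9), d = c(4, 1), e = c(0, 7))
  colnames(m) <- c("t1", "t2")
  res <- hierarchical_cluster(m, "average", k = 2)
  expect_equal(min(res$tree$height), 0)
  expect_true(!is.unsorted(res$tree$height))

  set.seed(22)
  m2 <- matrix(rnorm(10), 5, 2,
               dimnames = list(letters[1:5], c("t1", "t2")))
  z2 <- scale(m2)
  res2 <- hierarchical_cluster(m2, "average", k = 2)
  expect_equal(res2$tree$height, oracle_average_linkage(z2), tolerance = 1e-10)
})

test_that("cutting at k = n gives singletons whose means are the rows", {
  set.seed(23)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  res <- hierarchical_cluster(m, "ward", k = 4)
  expect_equal(sort(unname(res$assignment)), 1:4)
  for (e in rownames(m)) {
    expect_equal(unname(res$cluster_means[res$assignment[[e]], ]),
                 unname(m[e, ]))
  }
  dup <- m; rownames(dup) <- c("a", "a", "b", "c")
  expect_error(hierarchical_cluster(dup, "ward", k = 2), "duplicate")
  expect_error(hierarchical_cluster(m, "ward", k = 9), "between 1")
})

test_that("cluster shares reproduce the published cohort percentages", {
  expect_equal(cluster_shares(c(3, 10, 9, 8, 5)), c(8.6, 28.6, 25.7, 22.9, 14.3))
  expect_equal(cluster_shares(35), 100)
})

test_that("cluster profiles report size, share and mean +/- SEM per trait", {
  m <- trait_matrix(fixture_summaries(), "WD")
  res <- hierarchical_cluster(m, "ward", k = 5)
  prof <- cluster_profile(res, m)
  expect_equal(sum(unique(prof[c("cluster", "size")])$size), 35L)
  expect_equal(sum(unique(prof[c("cluster", "share_pct")])$share_pct), 100,
               tolerance = 0.2)
  single <- hierarchical_cluster(m, "ward", k = 1)
  prof1 <- cluster_profile(single, m)
  expect_true(all(prof1$share_pct == 100))
  expect_equal(prof1$mean[prof1$trait == "RWC"], mean(m[, "RWC"]))

  solo <- hierarchical_cluster(m[1:3, ], "ward", k = 3)
  prof3 <- cluster_profile(solo, m[1:3, ])
  expect_true(all(prof3$sem == 0))
})

test_that("clustering synthetic data recovers the planted tolerance classes", {
  trial <- simulate_trial(trial_config(seed = 101))
  truth <- trial$ground_truth$classes
  m <- trait_matrix(summarize_traits(trial$observations), "WD")
  res <- hierarchical_cluster(m, "ward", k = 3)
  # Rand index between planted classes and the k = 3 cut
  a <- res$assignment[truth$ecotype]
  b <- as.integer(factor(truth$class))
  pairs <- utils::combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  rand <- mean(same_a == same_b)
  expect_gt(rand, 0.6)
})
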