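#' Pairwise Pearson correlation matrix with significance
#'
#' Pearson r over the rows of an ecotype x trait matrix, with two-sided
#' p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom and significance codes at 0.05 / 0.01 / 0.001. Zero-variance
#' columns are flagged: their correlations are undefined and returned `NA`.
#'
#' @param matrix numeric matrix (rows = ecotypes, columns = traits), no
#'   missing cells, at least 3 rows.
#' @return a list of class `ds_corr` with `labels`, `r`, `p`, `stars`, `n`.
#' @export
correlation_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 3L) stop_input("need at least 3 rows")
  if (anyNA(m)) stop_input("matrix has missing cells")
  n <- nrow(m)
  constant <- apply(m, 2L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(m))
  if (any(constant)) {
    warning("zero-variance column(s): ", paste(colnames(m)[constant], collapse = ", "),
            call. = FALSE)
    r[constant, ] <- NA_real_; r[, constant] <- NA_real_
  }
  diag(r) <- ifelse(constant, NA_real_, 1)
  rr <- pmin(pmax(r, -1), 1)
  tval <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- ifelse(constant, NA_real_, 0)
  stars <- matrix(symnum(p, cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                         symbols = c("***", "**", "*", ""), na = "?",
                         corr = FALSE, legend = FALSE),
                  nrow(r), dimnames = dimnames(r))
  structure(list(labels = colnames(m), r = r, p = p, stars = stars, n = n),
            class = "ds_corr")
}

#' Principal component analysis of an ecotype x trait matrix
#'
#' Columns are centred and (by default) scaled to unit standard deviation
#' before decomposition, because the traits live on wildly different scales
#' (root length ~50 cm vs Fv/Fm ~0.2); an unstandardized decomposition would
#' be dominated by the largest-scaled trait. Component contributions are
#' `100 * eigenvalue / sum(eigenvalues)`. A deterministic sign convention is
#' applied: within each component, the loading of largest magnitude is made
#' positive, so repeated runs on identical input give identical scores.
#'
#' @param matrix numeric matrix (rows = ecotypes, columns = traits), at least
#'   2 rows and 2 columns, no missing cells.
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return a list of class `trait_pca` with `scores` (ecotypes x components),
#'   `loadings` (traits x components), `eigenvalues`, `contributions`
#'   (percent variance per component, summing to 100),
#'   `variable_contributions` (percent per trait within each component), and
#'   the centring/scaling vectors.
#' @export
trait_pca <- function(matrix, standardize = TRUE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) stop_input("need at least a 2 x 2 matrix")
  if (anyNA(m)) stop_input("matrix has missing cells")
  if (anyDuplicated(rownames(m))) stop_input("duplicate ecotype labels")
  if (standardize) {
    zero <- apply(m, 2L, stats::sd) == 0
    if (any(zero))
      stop_input("zero-variance column(s) cannot be standardized: ",
                 paste(colnames(m)[zero], collapse = ", "))
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  loadings <- fit$rotation
  scores <- fit$x
  # sign convention: dominant loading positive in every component
  for (j in seq_len(ncol(loadings))) {
    dom <- which.max(abs(loadings[, j]))
    if (loadings[dom, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- fit$sdev^2
  contributions <- 100 * eig / sum(eig)
  structure(list(
    scores = scores, loadings = loadings, eigenvalues = eig,
    contributions = contributions,
    variable_contributions = 100 * loadings^2,
    center = fit$center, scale = if (standardize) fit$scale else NULL
  ), class = "trait_pca")
}

#' Contribution-weighted ranking value of each genotype
#'
#' The drought-tolerance ranking value of genotype g is the sum over the
#' first `n_components` principal components of the component's percent
#' variance contribution times the genotype's score on that component:
#' `RV_g = sum_m contribution_m(%) * score_gm`. Genotypes are then given a
#' dense numerical rank 1..G by descending ranking value, with ties broken
#' by genotype identifier.
#'
#' @param pca a `trait_pca` object.
#' @param n_components number of leading components to combine (default 4).
#' @return a tibble of class `ranking_table` with `ecotype`, `PC1..PCm`
#'   score columns, `ranking_value` and `numerical_rank`.
#' @export
ranking_values <- function(pca, n_components = 4L) {
  stopifnot(inherits(pca, "trait_pca"))
  if (n_components > ncol(pca$scores))
    stop_input("n_components exceeds the ", ncol(pca$scores), " available components")
  idx <- seq_len(n_components)
  rv <- drop(pca$scores[, idx, drop = FALSE] %*% pca$contributions[idx])
  out <- tibble::as_tibble(pca$scores[, idx, drop = FALSE], rownames = "ecotype")
  out$ranking_value <- unname(rv)
  out$numerical_rank <- dense_rank_desc(out$ranking_value, out$ecotype)
  class(out) <- c("ranking_table", class(out))
  out
}

#' Dense descending rank with a stable identifier tie-break
#'
#' Rank 1 is the largest value; equal values receive consecutive ranks in
#' identifier order, so the ranks are always a permutation of 1..G.
#'
#' @param values numeric vector.
#' @param ids identifiers used to break ties.
#' @return integer vector of ranks.
#' @export
dense_rank_desc <- function(values, ids = seq_along(values)) {
  ord <- order(-values, ids, method = "radix")
  rank <- integer(length(values))
  rank[ord] <- seq_along(values)
  rank
}

#' Agglomerative hierarchical clustering of ecotypes
#'
#' Euclidean distances between standardized (z-scored) trait profiles,
#' agglomerated with Ward (default), average or complete linkage, and cut at
#' `k` clusters. Per-cluster means are reported on the original trait scale.
#'
#' @inheritParams trait_pca
#' @param linkage `"ward"` (Ward's D2), `"average"` or `"complete"`.
#' @param k number of clusters, `2 <= k <= nrow(matrix)` (or `1` for the
#'   degenerate single-cluster cut).
#' @return a list of class `cluster_result` with the `hclust` tree,
#'   `assignment` (named integer vector), `k`, `linkage`, and
#'   `cluster_means` (clusters x traits, original scale).
#' @export
hierarchical_cluster <- function(matrix, linkage = c("ward", "average", "complete"),
                                 k = 5L) {
  linkage <- match.arg(linkage)
  m <- as.matrix(matrix)
  if (anyNA(m)) stop_input("matrix has missing cells")
  if (anyDuplicated(rownames(m))) stop_input("duplicate ecotype labels")
  if (k < 1L || k > nrow(m))
    stop_input("k must be between 1 and the number of ecotypes (", nrow(m), ")")
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant traits carry no distance
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  tree <- stats::hclust(stats::dist(z), method = method)
  assignment <- stats::cutree(tree, k = k)
  means <- apply(m, 2L, function(col) tapply(col, assignment, mean))
  if (k == 1L) means <- matrix(means, nrow = 1L, dimnames = list("1", colnames(m)))
  structure(list(tree = tree, assignment = assignment, k = k,
                 linkage = linkage, cluster_means = means),
            class = "cluster_result")
}

#' Per-cluster trait profile
#'
#' Cluster sizes, share of the cohort in percent (one decimal), and mean with
#' SEM for every trait on the original scale.
#'
#' @param result a `cluster_result` from [hierarchical_cluster()].
#' @param matrix the ecotype x trait matrix the clustering was computed on.
#' @return a tibble with one row per cluster x trait plus `size` and
#'   `share_pct`.
#' @export
cluster_profile <- function(result, matrix) {
  m <- as.matrix(matrix)
  a <- result$assignment[rownames(m)]
  if (anyNA(a)) stop_input("matrix rows do not match the clustered ecotypes")
  sizes <- table(a)
  shares <- cluster_shares(as.integer(sizes))
  rows <- lapply(names(sizes), function(cl) {
    sub <- m[a == cl, , drop = FALSE]
    tibble::tibble(
      cluster = cl, size = as.integer(sizes[[cl]]),
      share_pct = shares[[match(cl, names(sizes))]],
      trait = colnames(m),
      mean = unname(colMeans(sub)),
      sem = if (nrow(sub) == 1L) 0
            else unname(apply(sub, 2L, stats::sd)) / sqrt(nrow(sub))
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort share of each cluster in percent
#'
#' @param sizes integer vector of cluster sizes.
#' @param digits decimals to round to (default 1, as published tables do).
#' @return numeric vector, `round(100 * sizes / sum(sizes), digits)`.
#' @examples
#' cluster_shares(c(3, 10, 9, 8, 5))  # 8.6 28.6 25.7 22.9 14.3
#' @export
cluster_shares <- function(sizes, digits = 1L) {
  if (any(sizes <= 0)) stop_input("cluster sizes must be positive")
  round(100 * sizes / sum(sizes), digits)
}
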