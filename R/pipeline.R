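#' Run the full drought-screening analysis and write a report bundle
#'
#' Orchestrates every stage on one dataset and writes the results, in order,
#' to `out_dir`: trait summaries, one split-plot ANOVA table per trait (only
#' when replicate-level observations are supplied), the stress-response
#' table, the drought-index table (when a yield trait or yield pairs are
#' available), per-regime correlation matrices, per-regime PCA outputs
#' (scores, loadings, contributions), the contribution-weighted ranking
#' table (computed on the water-deficit PCA), and cluster assignments with
#' their profile. A `manifest.json` records the configuration, package
#' version, seed and an MD5 checksum of every file; identical inputs and
#' configuration give byte-identical bundles. Any stage failure aborts with
#' the stage name, and the manifest marks the bundle incomplete.
#'
#' @param data either a long observation tibble (see [read_trait_table()] or
#'   [simulate_trial()]), or a `ds_summary` table of per-ecotype means (as
#'   returned by [fixture_summaries()]) when replicate data are unavailable.
#' @param out_dir output directory, created if needed.
#' @param yields optional tibble `ecotype, Ys, Yp`; defaults to yield pairs
#'   derived from the `DMY` trait when present in `data`.
#' @param alpha significance level for ANOVA/LSD (default 0.05).
#' @param n_components components entering the ranking value (default 4).
#' @param k number of clusters (default 5).
#' @param linkage clustering linkage (default `"ward"`).
#' @param seed recorded in the manifest; the analysis itself is
#'   deterministic.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(data, out_dir, yields = NULL, alpha = 0.05,
                         n_components = 4L, k = 5L,
                         linkage = c("ward", "average", "complete"),
                         seed = 1L) {
  linkage <- match.arg(linkage)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "droughtscreen",
    version = as.character(utils::packageVersion("droughtscreen")),
    config = list(alpha = alpha, n_components = n_components, k = k,
                  linkage = linkage, seed = seed),
    complete = FALSE, files = list()
  )
  written <- character(0)
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  save_manifest <- function() {
    manifest$files <- as.list(tools::md5sum(written))
    names(manifest$files) <- basename(written)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      save_manifest()
      stop_input("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  has_replicates <- !inherits(data, "ds_summary") && "value" %in% names(data)
  summaries <- stage("summarize",
    if (has_replicates) summarize_traits(data) else data)
  n_ecotypes <- length(unique(summaries$ecotype))
  if (k > n_ecotypes)
    stop_input("stage 'cluster' invalid: k = ", k, " exceeds the ",
               n_ecotypes, " ecotypes in the data")
  emit("summaries.csv", summaries)

  if (has_replicates) {
    stage("anova", for (tr in unique(data$trait)) {
      emit(paste0("anova_", gsub("[^A-Za-z0-9]", "", tr), ".csv"),
           splitplot_anova(data, tr))
    })
  }

  responses <- stage("stress_response", response_table(summaries))
  emit("stress_responses.csv", responses)

  if (is.null(yields) && "DMY" %in% summaries$trait && has_replicates)
    yields <- yield_pairs(data)
  if (!is.null(yields)) {
    indices <- stage("indices", compute_indices(yields))
    emit("indices.csv", indices)
  }

  pca_wd <- NULL
  for (regime in c("WS", "WD")) {
    mat <- stage(paste0("matrix_", regime), trait_matrix(summaries, regime))
    corr <- stage(paste0("correlation_", regime), correlation_matrix(mat))
    emit(paste0("correlation_", regime, ".csv"),
         cbind(trait = rownames(corr$r), as.data.frame(corr$r)))
    pca <- stage(paste0("pca_", regime), trait_pca(mat))
    emit(paste0("pca_", regime, "_scores.csv"),
         cbind(ecotype = rownames(pca$scores), as.data.frame(pca$scores)))
    emit(paste0("pca_", regime, "_loadings.csv"),
         cbind(trait = rownames(pca$loadings), as.data.frame(pca$loadings)))
    emit(paste0("pca_", regime, "_contributions.csv"),
         data.frame(component = seq_along(pca$contributions),
                    contribution_pct = pca$contributions))
    if (regime == "WD") {
      pca_wd <- pca
      ranking <- stage("ranking", ranking_values(pca, n_components))
      emit("ranking.csv", ranking)
      cl <- stage("cluster", hierarchical_cluster(mat, linkage, k))
      emit("clusters.csv", tibble::tibble(ecotype = names(cl$assignment),
                                          cluster = unname(cl$assignment)))
      emit("cluster_profile.csv", cluster_profile(cl, mat))
    }
  }

  manifest$complete <- TRUE
  save_manifest()
  invisible(manifest)
}
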