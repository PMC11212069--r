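# build a balanced long observation table from a value array indexed
# [block, regime, ecotype]
make_obs <- function(values, trait = "PH") {
  d <- dim(values)
  grid <- expand.grid(block = seq_len(d[1]), water_regime = c("WS", "WD")[seq_len(d[2])],
                      ecotype = sprintf("E%d", seq_len(d[3])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(ecotype = grid$ecotype, water_regime = grid$water_regime,
                 block = grid$block, trait = trait, value = as.vector(values))
}

# independent split-plot sums-of-squares oracle: direct summation over
# deviations of marginal means (no shortcut totals)
oracle_splitplot_ss <- function(obs) {
  y <- obs$value
  gm <- mean(y)
  mb <- tapply(y, obs$block, mean)[as.character(obs$block)]
  mr <- tapply(y, obs$water_regime, mean)[obs$water_regime]
  me <- tapply(y, obs$ecotype, mean)[obs$ecotype]
  mbr <- tapply(y, paste(obs$block, obs$water_regime), mean)[paste(obs$block, obs$water_regime)]
  mre <- tapply(y, paste(obs$water_regime, obs$ecotype), mean)[paste(obs$water_regime, obs$ecotype)]
  c(block = sum((mb - gm)^2),
    regime = sum((mr - gm)^2),
    error_a = sum((mbr - mb - mr + gm)^2),
    ecotype = sum((me - gm)^2),
    `regime:ecotype` = sum((mre - mr - me + gm)^2),
    error_b = sum((y - mbr - mre + mr)^2),
    total = sum((y - gm)^2))
}

# brute-force agglomerative clustering oracle: repeatedly merge the pair of
# clusters with the smallest average pairwise Euclidean distance
oracle_average_linkage <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
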