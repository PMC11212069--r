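#' Yield-based drought-tolerance indices
#'
#' Computes, for each ecotype with stress yield `Ys` and non-stress yield
#' `Yp` (per-ecotype mean dry matter yield, g/plant), the seven classical
#' selection indices:
#' \describe{
#'   \item{MP}{mean productivity, `(Ys + Yp) / 2`}
#'   \item{GMP}{geometric mean productivity, `sqrt(Ys * Yp)`}
#'   \item{TOL}{tolerance (yield loss), `Yp - Ys`}
#'   \item{YSI}{yield stability index, `Ys / Yp`}
#'   \item{YI}{yield index, `Ys / mean(Ys)`}
#'   \item{SSI}{stress susceptibility index, `(1 - Ys/Yp) / (1 - mean(Ys)/mean(Yp))`}
#'   \item{STI}{stress tolerance index, `(Ys * Yp) / mean(Yp)^2`}
#' }
#' Cohort means are arithmetic means over all ecotypes supplied. When the
#' cohort means under the two regimes coincide, SSI is undefined for the
#' whole cohort and returned as `NA` with a warning. Ecotypes with `Ys > Yp`
#' (negative TOL) are allowed but flagged.
#'
#' @param pairs a tibble/data frame with columns `ecotype`, `Ys`, `Yp`
#'   (`Ys >= 0`, `Yp > 0`, at least two ecotypes).
#' @return a tibble of class `drought_index_table` with one row per ecotype
#'   and columns `ecotype`, `Ys`, `Yp`, `MP`, `GMP`, `TOL`, `YSI`, `YI`,
#'   `SSI`, `STI`; cohort means are in the `"cohort_means"` attribute.
#' @examples
#' compute_indices(data.frame(ecotype = c("a", "b"), Ys = c(1, 3), Yp = c(2, 4)))
#' @export
compute_indices <- function(pairs) {
  stopifnot(all(c("ecotype", "Ys", "Yp") %in% names(pairs)))
  if (nrow(pairs) < 2L) stop_input("need at least 2 ecotypes")
  if (anyDuplicated(pairs$ecotype)) stop_input("duplicate ecotype labels")
  if (any(pairs$Ys < 0) || any(pairs$Yp <= 0))
    stop_input("yields must satisfy Ys >= 0 and Yp > 0")
  ys_bar <- mean(pairs$Ys); yp_bar <- mean(pairs$Yp)
  flagged <- pairs$ecotype[pairs$Ys > pairs$Yp]
  if (length(flagged))
    warning("Ys > Yp (negative TOL) for: ", paste(flagged, collapse = ", "),
            call. = FALSE)
  if (ys_bar == yp_bar) {
    warning("cohort means equal under both regimes: SSI undefined", call. = FALSE)
    ssi <- rep(NA_real_, nrow(pairs))
  } else {
    ssi <- (1 - pairs$Ys / pairs$Yp) / (1 - ys_bar / yp_bar)
  }
  out <- tibble::tibble(
    ecotype = pairs$ecotype, Ys = pairs$Ys, Yp = pairs$Yp,
    MP = (pairs$Ys + pairs$Yp) / 2,
    GMP = sqrt(pairs$Ys * pairs$Yp),
    TOL = pairs$Yp - pairs$Ys,
    YSI = pairs$Ys / pairs$Yp,
    YI = pairs$Ys / ys_bar,
    SSI = ssi,
    STI = pairs$Ys * pairs$Yp / yp_bar^2
  )
  attr(out, "cohort_means") <- c(Ys = ys_bar, Yp = yp_bar)
  class(out) <- c("drought_index_table", class(out))
  out
}

# larger value = more tolerant/productive? direction metadata per index
.index_direction <- c(Ys = "desc", Yp = "desc", MP = "desc", GMP = "desc",
                      TOL = "asc", YSI = "desc", YI = "desc",
                      SSI = "asc", STI = "desc")

#' Rank ecotypes by one drought-tolerance index
#'
#' Descending order for the productivity-type indices (MP, GMP, YI, STI and
#' the raw yields) where larger is better; ascending for SSI and TOL, where a
#' smaller value means less susceptibility / smaller absolute yield loss.
#' Ties are broken by ecotype identifier so the ordering is stable and
#' reproducible.
#'
#' @param table a `drought_index_table` from [compute_indices()].
#' @param index one of `Ys`, `Yp`, `MP`, `GMP`, `TOL`, `YSI`, `YI`, `SSI`, `STI`.
#' @param k return the top `k` ecotypes (default: all).
#' @return character vector of ecotype identifiers, most tolerant first.
#' @export
rank_by_index <- function(table, index, k = nrow(table)) {
  if (!index %in% names(.index_direction)) stop_input("unknown index: ", index)
  if (k > nrow(table)) stop_input("k exceeds cohort size")
  v <- table[[index]]
  ord <- if (.index_direction[[index]] == "desc") {
    order(-v, table$ecotype, method = "radix")
  } else {
    order(v, table$ecotype, method = "radix")
  }
  table$ecotype[ord][seq_len(k)]
}

#' Correlations among yields and drought-tolerance indices
#'
#' Pearson correlations (with two-sided p-values from the t approximation)
#' among `Ys`, `Yp` and the seven indices across the cohort. Zero-variance
#' columns are flagged and their correlations set to `NA`.
#'
#' @param table a `drought_index_table` from [compute_indices()].
#' @return a `ds_corr` object (see [correlation_matrix()]).
#' @export
index_correlations <- function(table) {
  if (nrow(table) < 3L) stop_input("need at least 3 ecotypes")
  cols <- intersect(c("Ys", "Yp", "MP", "GMP", "TOL", "YSI", "YI", "SSI", "STI"),
                    names(table))
  m <- as.matrix(table[cols])
  rownames(m) <- table$ecotype
  correlation_matrix(m)
}
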