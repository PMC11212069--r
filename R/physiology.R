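#' Relative water content of a leaf sample
#'
#' RWC = (FWT - DW) / (TW - DW) x 100, where FWT is the fresh weight of the
#' youngest fully expanded leaf, TW its turgid weight after rehydration, and
#' DW its oven-dry weight. A well-formed sample satisfies TW >= FWT >= DW > 0;
#' a turgid weight at or below the dry weight makes the ratio degenerate and
#' is an error, while a fresh weight outside \[DW, TW\] is flagged as a
#' measurement inconsistency and yields `NA` with a warning.
#'
#' @param fwt,tw,dw numeric vectors of fresh, turgid and dry weight (g).
#' @return RWC in percent, in \[0, 100\].
#' @examples
#' relative_water_content(6, 10, 2)  # 50
#' @export
relative_water_content <- function(fwt, tw, dw) {
  if (any(!is.finite(fwt) | !is.finite(tw) | !is.finite(dw)))
    stop_input("weights must be finite numbers")
  if (any(dw <= 0)) stop_input("dry weight must be positive")
  if (any(tw <= dw)) stop_input("turgid weight must exceed dry weight (degenerate denominator)")
  out <- (fwt - dw) / (tw - dw) * 100
  bad <- fwt < dw | fwt > tw
  if (any(bad)) {
    warning(sum(bad), " sample(s) with fresh weight outside [dry, turgid];",
            " flagged as measurement inconsistency (NA)", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Signed stress response relative to the well-watered mean
#'
#' Percent change of the water-deficit mean relative to the water-sufficient
#' mean: `(mean_WD - mean_WS) / mean_WS * 100`. Negative values are
#' reductions, positive values increases.
#'
#' @param mean_ws,mean_wd numeric vectors of trait means under the two
#'   regimes; a zero `mean_ws` makes the change undefined (`NA`, flagged).
#' @return a tibble with `mean_WS`, `mean_WD`, `pct_change` and `direction`
#'   (`decrease` / `increase` / `unchanged`).
#' @examples
#' stress_response(14.9, 8.37)  # -43.8 %
#' @export
stress_response <- function(mean_ws, mean_wd) {
  pct <- ifelse(mean_ws == 0, NA_real_, (mean_wd - mean_ws) / mean_ws * 100)
  if (any(mean_ws == 0))
    warning("pct_change undefined where the well-watered mean is 0", call. = FALSE)
  tibble::tibble(
    mean_WS = mean_ws, mean_WD = mean_wd, pct_change = pct,
    direction = dplyr::case_when(
      is.na(pct) ~ NA_character_,
      pct < 0 ~ "decrease", pct > 0 ~ "increase", TRUE ~ "unchanged"
    )
  )
}

#' Stress-response table over ecotypes and traits
#'
#' Joins per-ecotype trait means from the two regimes and reports the signed
#' percent change for every ecotype x trait cell, plus one `ALL` row per
#' trait computed from the grand means. When the input carries a `"footer"`
#' attribute with published grand means (as the packaged fixtures do) those
#' are used for the `ALL` rows at their printed precision; otherwise the
#' grand mean is the arithmetic mean of the per-ecotype means. Ecotypes
#' present under only one regime are skipped with a warning.
#'
#' @param summaries a `ds_summary` tibble covering both regimes, or the WS
#'   half when `summaries_wd` is given separately.
#' @param summaries_wd optional `ds_summary` tibble with the WD half.
#' @param sort_by_magnitude order rows by `|pct_change|`, largest first.
#' @return a tibble with `ecotype` (`"ALL"` for the grand-mean rows),
#'   `trait`, `mean_WS`, `mean_WD`, `pct_change`, `direction`.
#' @examples
#' responses <- response_table(fixture_summaries())
#' subset(responses, ecotype == "ALL")
#' @export
response_table <- function(summaries, summaries_wd = NULL,
                           sort_by_magnitude = FALSE) {
  footer <- attr(summaries, "footer")
  if (!is.null(summaries_wd)) {
    footer <- footer %||% attr(summaries_wd, "footer")
    summaries <- dplyr::bind_rows(summaries, summaries_wd)
  }
  ws <- summaries[summaries$water_regime == "WS", c("ecotype", "trait", "mean")]
  wd <- summaries[summaries$water_regime == "WD", c("ecotype", "trait", "mean")]
  unmatched <- union(setdiff(ws$ecotype, wd$ecotype), setdiff(wd$ecotype, ws$ecotype))
  if (length(unmatched))
    warning("skipping ecotype(s) without both regimes: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  cells <- dplyr::inner_join(ws, wd, by = c("ecotype", "trait"),
                             suffix = c("_WS", "_WD"))
  per_ecotype <- dplyr::bind_cols(
    cells[c("ecotype", "trait")],
    stress_response(cells$mean_WS, cells$mean_WD)
  )

  if (!is.null(footer)) {
    grand <- tidyr::pivot_wider(footer[c("trait", "water_regime", "grand_mean")],
                                names_from = "water_regime", values_from = "grand_mean")
  } else {
    grand <- per_ecotype |>
      dplyr::group_by(.data$trait) |>
      dplyr::summarise(WS = mean(.data$mean_WS), WD = mean(.data$mean_WD),
                       .groups = "drop")
  }
  grand <- grand[grand$trait %in% unique(per_ecotype$trait), , drop = FALSE]
  all_rows <- dplyr::bind_cols(
    tibble::tibble(ecotype = "ALL", trait = grand$trait),
    stress_response(grand$WS, grand$WD)
  )
  out <- dplyr::bind_rows(per_ecotype, all_rows)
  if (sort_by_magnitude) out <- out[order(-abs(out$pct_change)), ]
  out
}
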