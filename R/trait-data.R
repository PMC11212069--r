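#' Read a long- or wide-format trait observation table
#'
#' The long dialect expects columns `ecotype, water_regime, block, trait,
#' value`; the wide dialect expects `ecotype, water_regime, block` plus one
#' column per trait (headers are matched case-insensitively against the
#' registered vocabulary, so `Fv/Fm` and `FvFm` are equivalent). Values are
#' parsed strictly: rows whose value field is not a well-formed number (for
#' example the run-together token `6.20.37`) are rejected, and the rejection
#' message lists the file line number and the offending token.
#'
#' @param path path to a UTF-8 CSV file with `.` as the decimal separator.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param allow_custom_traits accept trait names outside the registry.
#' @return A tibble of validated observations (`ecotype`, `water_regime`,
#'   `block`, `trait`, `value`). Rejected rows are reported via a warning and
#'   recorded in the `"rejected"` attribute.
#' @export
read_trait_table <- function(path, dialect = c("long", "wide"),
                             allow_custom_traits = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE, fileEncoding = "UTF-8")
  if (dialect == "wide") raw <- .wide_to_long(raw, allow_custom_traits)
  required <- c("ecotype", "water_regime", "block", "trait", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_input("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("file contains a header but no observations: ", path, call. = FALSE)
    return(.empty_observations())
  }

  value <- suppressWarnings(as.numeric(raw$value))
  block <- suppressWarnings(as.integer(raw$block))
  bad_value <- is.na(value) & nzchar(raw$value)
  bad_block <- is.na(block)
  rejected <- which(bad_value | bad_block)
  if (length(rejected)) {
    # +1 for the header line so the numbers match the file
    detail <- sprintf("line %d: value '%s'", rejected + 1L,
                      ifelse(bad_value[rejected], raw$value[rejected], raw$block[rejected]))
    warning("rejected ", length(rejected), " malformed row(s):\n  ",
            paste(detail, collapse = "\n  "), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), rejected)
  obs <- tibble::tibble(
    ecotype = raw$ecotype[keep],
    water_regime = toupper(raw$water_regime[keep]),
    block = block[keep],
    trait = canonical_trait(raw$trait[keep], allow_custom_traits),
    value = value[keep]
  )
  validate_observations(obs, allow_custom_traits)
  attr(obs, "rejected") <- rejected + 1L
  obs
}

.empty_observations <- function() {
  tibble::tibble(ecotype = character(), water_regime = character(),
                 block = integer(), trait = character(), value = double())
}

.wide_to_long <- function(raw, allow_custom_traits) {
  id <- c("ecotype", "water_regime", "block")
  missing <- setdiff(id, names(raw))
  if (length(missing))
    stop_input("missing required column(s): ", paste(missing, collapse = ", "))
  trait_cols <- setdiff(names(raw), id)
  if (!length(trait_cols)) stop_input("wide table has no trait columns")
  names(raw)[match(trait_cols, names(raw))] <-
    canonical_trait(trait_cols, allow_custom_traits)
  tidyr::pivot_longer(raw, cols = !dplyr::all_of(id),
                      names_to = "trait", values_to = "value")
}

#' @rdname read_trait_table
#' @param observations a tibble of observations as returned by
#'   [read_trait_table()] or [simulate_trial()].
#' @export
write_trait_table <- function(observations, path) {
  utils::write.csv(as.data.frame(observations), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Validate a set of trait observations
#'
#' Checks the domain of every value against the trait registry (counts
#' non-negative, proportions in \[0, 1\], percentages in \[0, 100\], all values
#' finite) and that the key `(ecotype, water_regime, block, trait)` is unique.
#'
#' @inheritParams write_trait_table
#' @param allow_custom_traits skip domain checks for unregistered traits.
#' @return the observations, invisibly; errors describe every violation.
#' @export
validate_observations <- function(observations, allow_custom_traits = FALSE) {
  if (!all(observations$water_regime %in% c("WS", "WD")))
    stop_input("water_regime must be 'WS' or 'WD'")
  if (any(observations$block < 1L, na.rm = TRUE))
    stop_input("block must be a positive integer")
  msg <- check_trait_domain(observations$trait, observations$value)
  if (length(msg)) stop_input("invalid observation(s):\n  ", paste(msg, collapse = "\n  "))
  key <- paste(observations$ecotype, observations$water_regime,
               observations$block, observations$trait)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_input("duplicate observation key(s): ", paste(utils::head(dup, 5L), collapse = "; "))
  }
  invisible(observations)
}

#' Summarize replicate observations to mean and SEM
#'
#' One row per (ecotype, water_regime, trait) cell with the arithmetic mean,
#' the standard error of the mean (sample standard deviation over the square
#' root of the replicate count) and `n`. Cells with a single replicate get
#' `sem = 0` with a warning.
#'
#' @inheritParams write_trait_table
#' @return a tibble of class `ds_summary` with columns `ecotype`,
#'   `water_regime`, `trait`, `mean`, `sem`, `n`.
#' @examples
#' obs <- tibble::tibble(ecotype = "A", water_regime = "WS", block = 1:3,
#'                       trait = "PH", value = c(10, 12, 14))
#' summarize_traits(obs)
#' @export
summarize_traits <- function(observations) {
  out <- observations |>
    dplyr::group_by(.data$ecotype, .data$water_regime, .data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = ifelse(dplyr::n() == 1L, 0, stats::sd(.data$value) / sqrt(dplyr::n())),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n == 1L))
    warning("cells with a single replicate have sem = 0", call. = FALSE)
  class(out) <- c("ds_summary", class(out))
  out
}

#' Assemble an ecotype-by-trait matrix of means for one water regime
#'
#' Rows are ecotypes in their input order, columns the requested traits.
#' Ecotypes missing any requested trait (and traits missing for all ecotypes
#' already summarized) are dropped with a warning; no values are imputed.
#'
#' @param summaries a `ds_summary` tibble (or any tibble with `ecotype`,
#'   `water_regime`, `trait`, `mean`).
#' @param water_regime `"WS"` or `"WD"`.
#' @param traits character vector of traits to include; defaults to every
#'   trait present for the regime.
#' @return a numeric matrix with ecotype row names and trait column names;
#'   dropped ecotypes are recorded in the `"dropped"` attribute.
#' @export
trait_matrix <- function(summaries, water_regime, traits = NULL) {
  stopifnot(water_regime %in% c("WS", "WD"))
  sub <- summaries[summaries$water_regime == water_regime, , drop = FALSE]
  if (nrow(sub) == 0L) stop_input("no summaries for regime ", water_regime)
  traits <- traits %||% unique(sub$trait)
  absent <- setdiff(traits, unique(sub$trait))
  if (length(absent))
    stop_input("trait(s) absent for all ecotypes under ", water_regime, ": ",
               paste(absent, collapse = ", "))
  ecotypes <- unique(sub$ecotype)
  m <- matrix(NA_real_, length(ecotypes), length(traits),
              dimnames = list(ecotypes, traits))
  sub <- sub[sub$trait %in% traits, , drop = FALSE]
  m[cbind(match(sub$ecotype, ecotypes), match(sub$trait, traits))] <- sub$mean
  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete)) {
    warning("dropping ecotype(s) with missing traits: ",
            paste(ecotypes[incomplete], collapse = ", "), call. = FALSE)
    m <- m[!incomplete, , drop = FALSE]
  }
  attr(m, "dropped") <- ecotypes[incomplete]
  attr(m, "water_regime") <- water_regime
  m
}

#' Load a packaged reference table
#'
#' The package ships, as plain CSV, the published per-ecotype trait tables of
#' a 35-ecotype Urochloa grass drought screen: `table1` (morphology: PH, NT,
#' NL, RL), `table2` (physiology: RWC, Phi2, PhiNPQ, SPAD, FvFm), both as
#' mean and SEM per ecotype and water regime with the published grand-mean /
#' CV% / LSD footer rows attached as the `"footer"` attribute; `table4` (the
#' published PC1--PC4 scores, mean ranking value and numerical rank per
#' ecotype under water deficit); and `cluster_sizes` (the published
#' five-cluster partition sizes). Transcription notes, including the handling
#' of typographic defects in the source tables, are attached as the
#' `"notes"` attribute (see `fixture_notes.json` in `inst/extdata`).
#'
#' @param name one of `"table1"`, `"table2"`, `"table4"`, `"cluster_sizes"`.
#' @return `table1`/`table2`: a `ds_summary` tibble (long format, `n = 3`
#'   replicates as published) with `"footer"` and `"notes"` attributes.
#'   `table4` and `cluster_sizes`: tibbles mirroring the published tables.
#' @examples
#' t1 <- load_fixture("table1")
#' attr(t1, "footer")
#' @export
load_fixture <- function(name = c("table1", "table2", "table4", "cluster_sizes")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "droughtscreen", mustWork = TRUE)
  notes <- jsonlite::read_json(path("fixture_notes.json"), simplifyVector = TRUE)[[name]]
  if (name %in% c("table1", "table2")) {
    wide <- tibble::as_tibble(utils::read.csv(path(paste0(name, ".csv"))))
    long <- tidyr::pivot_longer(wide, cols = -"ecotype",
                                names_to = c("trait", "water_regime", ".value"),
                                names_sep = "_")
    long$n <- 3L
    footer <- tibble::as_tibble(utils::read.csv(path(paste0(name, "_footer.csv"))))
    class(long) <- c("ds_summary", class(long))
    attr(long, "footer") <- footer
    attr(long, "notes") <- notes
    return(long)
  }
  out <- tibble::as_tibble(utils::read.csv(path(paste0(name, ".csv"))))
  attr(out, "notes") <- notes
  out
}

#' Combined published trait summaries (morphology + physiology)
#'
#' Convenience wrapper that row-binds the `table1` and `table2` fixtures into
#' one `ds_summary` table covering nine traits, with the two footers
#' concatenated.
#'
#' @return a `ds_summary` tibble with `"footer"` and `"notes"` attributes.
#' @export
fixture_summaries <- function() {
  t1 <- load_fixture("table1"); t2 <- load_fixture("table2")
  out <- dplyr::bind_rows(t1, t2)
  class(out) <- c("ds_summary", class(out))
  attr(out, "footer") <- dplyr::bind_rows(attr(t1, "footer"), attr(t2, "footer"))
  attr(out, "notes") <- c(attr(t1, "notes"), attr(t2, "notes"))
  out
}
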