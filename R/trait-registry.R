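#' Registered trait vocabulary
#'
#' The package validates observations against a closed registry of the eleven
#' morpho-physiological and yield traits measured in greenhouse drought
#' screens: plant height (PH), tiller number (NT), leaf number (NL), root
#' length (RL), shoot fresh weight (FWT), dry matter yield (DMY), relative
#' water content (RWC), photosystem II photochemistry (Phi2),
#' non-photochemical quenching (PhiNPQ), relative chlorophyll content (SPAD)
#' and maximum PSII efficiency (FvFm). Each trait carries a unit, an
#' admissible domain used by validation, and the link scale on which the
#' synthetic generator draws Gaussian errors (log for positive quantities and
#' counts, logit for proportions) so simulated values respect the domain.
#'
#' @return A tibble with columns `trait`, `unit`, `kind` (one of `positive`,
#'   `count`, `proportion`, `percentage`), `lower`, `upper`, and `link`.
#' @examples
#' trait_registry()
#' @export
trait_registry <- function() {
  tibble::tribble(
    ~trait,    ~unit,      ~kind,         ~lower, ~upper, ~link,
    "PH",      "cm",       "positive",    0,      Inf,    "log",
    "NT",      "count",    "count",       0,      Inf,    "log",
    "NL",      "count",    "count",       0,      Inf,    "log",
    "RL",      "cm",       "positive",    0,      Inf,    "log",
    "FWT",     "g",        "positive",    0,      Inf,    "log",
    "DMY",     "g/plant",  "positive",    0,      Inf,    "log",
    "RWC",     "%",        "percentage",  0,      100,    "logit",
    "Phi2",    "fraction", "proportion",  0,      1,      "logit",
    "PhiNPQ",  "fraction", "proportion",  0,      1,      "logit",
    "SPAD",    "SPAD",     "positive",    0,      Inf,    "log",
    "FvFm",    "fraction", "proportion",  0,      1,      "logit"
  )
}

# case-insensitive alias table: header spellings seen in the wild -> canonical
.trait_aliases <- c(
  "fv/fm" = "FvFm", "fvfm" = "FvFm", "fv_fm" = "FvFm",
  "phi2" = "Phi2", "phipsii" = "Phi2", "phinpq" = "PhiNPQ", "npq" = "PhiNPQ",
  "ph" = "PH", "nt" = "NT", "nl" = "NL", "rl" = "RL",
  "fwt" = "FWT", "dmy" = "DMY", "rwc" = "RWC", "spad" = "SPAD"
)

#' Map trait names or column headers onto the registered vocabulary
#'
#' @param x character vector of trait names as found in a file header.
#' @param allow_custom keep unrecognised names as-is instead of erroring.
#' @return character vector of canonical trait names.
#' @export
canonical_trait <- function(x, allow_custom = FALSE) {
  key <- tolower(trimws(x))
  out <- unname(.trait_aliases[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    if (!allow_custom)
      stop_input("unknown trait name(s): ", paste(unique(x[unknown]), collapse = ", "),
                 " (set allow_custom = TRUE to accept unregistered traits)")
    out[unknown] <- x[unknown]
  }
  out
}

# per-value domain check; returns character vector of violation messages
check_trait_domain <- function(trait, value) {
  reg <- trait_registry()
  i <- match(trait, reg$trait)
  msg <- character(0)
  bad <- !is.finite(value)
  if (any(bad)) msg <- c(msg, sprintf("non-finite value for trait %s", trait[bad]))
  known <- !is.na(i) & is.finite(value)
  lo <- reg$lower[i]; hi <- reg$upper[i]
  oob <- known & (value < lo | value > hi)
  if (any(oob))
    msg <- c(msg, sprintf("value %g outside [%g, %g] for trait %s",
                          value[oob], lo[oob], hi[oob], trait[oob]))
  msg
}
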