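#' Split-plot analysis of variance for one trait
#'
#' Standard two-factor split-plot decomposition for a randomized complete
#' block trial with the water regime applied to whole plots and the ecotype
#' to sub-plots: sources are block, regime, error(a) = block x regime,
#' ecotype, regime x ecotype, error(b) = remainder. The regime F-test uses
#' MS error(a) as denominator; ecotype and interaction use MS error(b). Sums
#' of squares come from the closed-form balanced decomposition over marginal
#' means, so SS and df are exactly additive.
#'
#' @param observations a long observation tibble (see [read_trait_table()]).
#' @param trait the trait to analyse.
#' @return a tibble of class `splitplot_anova` with columns `source`, `df`,
#'   `SS`, `MS`, `F`, `p`.
#' @examples
#' trial <- simulate_trial(trial_config(n_ecotypes = 6, n_blocks = 3, seed = 1))
#' splitplot_anova(trial$observations, "DMY")
#' @export
splitplot_anova <- function(observations, trait) {
  d <- observations[observations$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop_input("no observations for trait ", trait)
  blocks <- sort(unique(d$block)); regimes <- sort(unique(d$water_regime))
  ecot <- unique(d$ecotype)
  b <- length(blocks); r <- length(regimes); g <- length(ecot)
  if (b < 2L) stop_input("split-plot ANOVA needs at least 2 blocks")
  tab <- table(d$block, d$water_regime, d$ecotype)
  if (any(tab != 1L)) {
    miss <- which(tab == 0L, arr.ind = TRUE)
    detail <- apply(utils::head(miss, 10L), 1L, function(i)
      paste0("(block ", dimnames(tab)[[1]][i[1]], ", ", dimnames(tab)[[2]][i[2]],
             ", ", dimnames(tab)[[3]][i[3]], ")"))
    stop_input("unbalanced design for trait ", trait, "; missing/duplicated cells: ",
               paste(detail, collapse = ", "))
  }
  y <- d$value
  N <- length(y)
  C <- sum(y)^2 / N
  ss_total <- sum(y^2) - C
  tot <- function(...) tapply(y, list(...), sum)
  ss_block  <- sum(tot(d$block)^2) / (r * g) - C
  ss_regime <- sum(tot(d$water_regime)^2) / (b * g) - C
  ss_err_a  <- sum(tot(d$block, d$water_regime)^2) / g - C - ss_block - ss_regime
  ss_eco    <- sum(tot(d$ecotype)^2) / (b * r) - C
  ss_int    <- sum(tot(d$water_regime, d$ecotype)^2) / b - C - ss_regime - ss_eco
  ss_err_b  <- ss_total - ss_block - ss_regime - ss_err_a - ss_eco - ss_int

  df <- c(block = b - 1L, regime = r - 1L, error_a = (b - 1L) * (r - 1L),
          ecotype = g - 1L, `regime:ecotype` = (r - 1L) * (g - 1L),
          error_b = r * (b - 1L) * (g - 1L), total = N - 1L)
  SS <- c(ss_block, ss_regime, ss_err_a, ss_eco, ss_int, ss_err_b, ss_total)
  # numerical floor: tiny negative remainders from cancellation are zero
  SS[SS < 0 & SS > -1e-8 * max(ss_total, 1)] <- 0
  MS <- SS / df
  ms_a <- MS[3]; ms_b <- MS[6]
  Fval <- c(MS[1] / ms_a, MS[2] / ms_a, NA, MS[4] / ms_b, MS[5] / ms_b, NA, NA)
  if ((ms_a == 0 || df[3] == 0) || (ms_b == 0 || df[6] == 0)) {
    warning("zero error variance or zero error df: F statistics omitted",
            call. = FALSE)
    Fval[] <- NA_real_
  }
  pval <- stats::pf(Fval, df, c(df[3], df[3], NA, df[6], df[6], NA, NA),
                    lower.tail = FALSE)
  out <- tibble::tibble(source = names(df), df = as.integer(unname(df)),
                        SS = unname(SS), MS = unname(MS), F = unname(Fval),
                        p = unname(pval))
  class(out) <- c("splitplot_anova", class(out))
  out
}

#' Least significant difference for a pair of means
#'
#' `t(1 - alpha/2, df) * sqrt(2 * ms_error / n)`, the minimum absolute
#' difference between two means (each over `n` observations) declared
#' significant at level `alpha`.
#'
#' @param ms_error error mean square of the relevant stratum.
#' @param n number of observations per mean.
#' @param df error degrees of freedom.
#' @param alpha significance level in (0, 1).
#' @export
lsd_value <- function(ms_error, n, df, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (df < 1) stop_input("error df must be >= 1")
  stats::qt(1 - alpha / 2, df) * sqrt(2 * ms_error / n)
}

#' LSD mean separation of ecotypes within one water regime
#'
#' Fits a randomized-complete-block model (block + ecotype) within the given
#' regime, computes the LSD from its residual mean square, and assigns
#' compact letter codes by the standard sweep over means in descending order:
#' two ecotypes share a letter if and only if their means differ by at most
#' the LSD. One LSD per regime matches how screening trials report a separate
#' LSD column for each regime.
#'
#' @inheritParams splitplot_anova
#' @param water_regime `"WS"` or `"WD"`.
#' @param alpha significance level.
#' @return a list of class `lsd_result` with `trait`, `water_regime`,
#'   `lsd_value`, and `groups` (tibble: `ecotype`, `mean`, `letters`).
#' @export
lsd_separation <- function(observations, trait, water_regime, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  fit <- .rcbd_fit(observations, trait, water_regime)
  if (fit$df_error < 1L) stop_input("error df < 1; cannot compute LSD")
  lsd <- lsd_value(fit$ms_error, fit$n_per_mean, fit$df_error, alpha)
  means <- sort(fit$means, decreasing = TRUE)
  letters_by_mean <- .sweep_letters(means, lsd)
  groups <- tibble::tibble(ecotype = names(means), mean = unname(means),
                           letters = letters_by_mean)
  structure(list(trait = trait, water_regime = water_regime, alpha = alpha,
                 lsd_value = lsd, groups = groups), class = "lsd_result")
}

#' Coefficient of variation within one water regime
#'
#' `sqrt(MS_error) / grand_mean * 100` from the within-regime
#' randomized-complete-block fit, matching the CV% rows of published trait
#' tables.
#'
#' @inheritParams lsd_separation
#' @return CV in percent; `NA` with a warning when the grand mean is 0.
#' @export
cv_percent <- function(observations, trait, water_regime) {
  fit <- .rcbd_fit(observations, trait, water_regime)
  if (fit$grand_mean == 0) {
    warning("grand mean is 0: CV undefined", call. = FALSE)
    return(NA_real_)
  }
  sqrt(fit$ms_error) / fit$grand_mean * 100
}

# balanced RCBD (block + ecotype) closed-form fit within one regime
.rcbd_fit <- function(observations, trait, water_regime) {
  d <- observations[observations$trait == trait &
                      observations$water_regime == water_regime, , drop = FALSE]
  if (nrow(d) < 2L) stop_input("need at least 2 observations for ", trait,
                               " under ", water_regime)
  tab <- table(d$block, d$ecotype)
  if (any(tab != 1L)) stop_input("unbalanced block x ecotype layout for ",
                                 trait, " under ", water_regime)
  b <- nrow(tab); g <- ncol(tab)
  y <- d$value
  C <- sum(y)^2 / length(y)
  ss_total <- sum(y^2) - C
  ss_block <- sum(tapply(y, d$block, sum)^2) / g - C
  ss_eco <- sum(tapply(y, d$ecotype, sum)^2) / b - C
  ss_err <- max(ss_total - ss_block - ss_eco, 0)
  df_err <- (b - 1L) * (g - 1L)
  list(means = tapply(y, d$ecotype, mean),
       grand_mean = mean(y),
       ms_error = if (df_err > 0) ss_err / df_err else NA_real_,
       df_error = df_err, n_per_mean = b)
}

# compact letter display: maximal runs of mutually non-significant means
# (means sorted in decreasing order)
.sweep_letters <- function(means, lsd) {
  k <- length(means)
  ends <- integer(k)
  for (i in seq_len(k)) ends[i] <- max(which(means[i] - means <= lsd))
  # keep only maximal intervals [i, ends[i]]
  keep <- !duplicated(ends)
  starts <- which(keep); stops <- ends[keep]
  inner <- c(FALSE, (starts[-1] >= starts[-length(starts)]) &
               (stops[-length(stops)] >= stops[-1]))
  starts <- starts[!inner]; stops <- stops[!inner]
  labs <- rep("", k)
  for (j in seq_along(starts)) {
    idx <- starts[j]:stops[j]
    labs[idx] <- paste0(labs[idx], letters[(j - 1L) %% 26L + 1L])
  }
  labs
}
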