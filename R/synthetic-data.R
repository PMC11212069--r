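#' Default per-trait generator parameters
#'
#' Means under water sufficiency (`mu_WS`) and the fractional drought effect
#' (`drought_effect`, so the expected water-deficit mean of a baseline
#' ecotype is `mu_WS * (1 + drought_effect)`) are anchored to the grand-mean
#' rows of the packaged reference tables; residual standard deviations (on
#' the link scale) follow the published CV% rows. PhiNPQ is the one trait
#' that increases under stress. FWT and DMY have no published per-ecotype
#' table; their anchors are the published grand reduction percentages (84 %
#' and 66.8 %) and a WS dry matter yield of ~4.1 g/plant implied by the
#' published per-cluster WD means.
#'
#' @return a tibble with columns `trait`, `mu_WS`, `drought_effect`,
#'   `sigma_block`, `sigma_wholeplot`, `sigma_ecotype`, `sigma_resid` (all
#'   sigmas on the link scale) and `link`.
#' @export
default_trait_params <- function() {
  tibble::tribble(
    ~trait,   ~mu_WS, ~drought_effect, ~sigma_block, ~sigma_wholeplot, ~sigma_ecotype, ~sigma_resid,
    "PH",     14.9,   -0.438,          0.05,         0.05,             0.30,           0.37,
    "NT",     5.07,   -0.241,          0.05,         0.05,             0.40,           0.50,
    "NL",     4.82,   -0.297,          0.05,         0.05,             0.15,           0.25,
    "RL",     75.53,  -0.315,          0.05,         0.05,             0.20,           0.22,
    "FWT",    6.0,    -0.84,           0.05,         0.05,             0.20,           0.35,
    "DMY",    4.1,    -0.668,          0.05,         0.05,             0.05,           0.35,
    "RWC",    74.27,  -0.859,          0.05,         0.05,             0.25,           0.30,
    "Phi2",   0.36,   -0.50,           0.05,         0.05,             0.25,           0.35,
    "PhiNPQ", 0.60,    0.283,          0.05,         0.05,             0.15,           0.24,
    "SPAD",   37.14,  -0.853,          0.05,         0.05,             0.10,           0.14,
    "FvFm",   0.41,   -0.439,          0.05,         0.05,             0.20,           0.29
  ) |>
    dplyr::left_join(trait_registry()[c("trait", "link", "kind")], by = "trait")
}

#' Configuration for a synthetic split-plot drought trial
#'
#' Describes a randomized complete block trial in split-plot arrangement:
#' the water regime (WS vs WD) is applied to whole plots within each block
#' and every ecotype occupies one sub-plot per whole plot. Each ecotype
#' carries a latent tolerance class whose multiplier scales the link-scale
#' regime shift, so tolerant ecotypes have the smallest expected relative
#' loss and sensitive ones the largest.
#'
#' @param n_ecotypes number of ecotypes (default 35).
#' @param n_blocks number of replicate blocks (default 5).
#' @param traits per-trait parameter tibble, see [default_trait_params()].
#' @param class_counts named integer vector over
#'   `c(tolerant, moderate, sensitive)` summing to `n_ecotypes`.
#' @param class_multipliers named numeric multipliers of the link-scale
#'   regime shift, non-decreasing from tolerant to sensitive (equal
#'   multipliers give a class-free null configuration).
#' @param seed master integer seed; every random stream derives from it.
#' @return a validated list of class `trial_config`.
#' @export
trial_config <- function(n_ecotypes = 35L, n_blocks = 5L,
                         traits = default_trait_params(),
                         class_counts = NULL,
                         class_multipliers = c(tolerant = 0.45, moderate = 1.0,
                                               sensitive = 1.6),
                         seed = 1L) {
  stopifnot(n_ecotypes >= 1L, n_blocks >= 1L)
  class_counts <- class_counts %||% .default_class_counts(n_ecotypes)
  if (sum(class_counts) != n_ecotypes)
    stop_input("class_counts must sum to n_ecotypes")
  need <- c("tolerant", "moderate", "sensitive")
  if (!all(need %in% names(class_multipliers)) ||
      is.unsorted(class_multipliers[need]))
    stop_input("class_multipliers must be non-decreasing from tolerant to sensitive")
  sig <- c("sigma_block", "sigma_wholeplot", "sigma_ecotype", "sigma_resid")
  if (any(is.na(as.matrix(traits[sig]))) || any(as.matrix(traits[sig]) < 0))
    stop_input("all sigmas must be non-negative numbers")
  if (any(!traits$link %in% c("log", "logit")))
    stop_input("unsupported link for trait(s): ",
               paste(traits$trait[!traits$link %in% c("log", "logit")], collapse = ", "))
  ok_mu <- ifelse(traits$link == "logit",
                  traits$mu_WS > 0 &
                    traits$mu_WS < ifelse(traits$kind == "percentage", 100, 1) &
                    traits$mu_WS * (1 + traits$drought_effect) > 0,
                  traits$mu_WS > 0 & traits$mu_WS * (1 + traits$drought_effect) > 0)
  if (any(!ok_mu))
    stop_input("mu_WS / drought_effect out of the trait domain for: ",
               paste(traits$trait[!ok_mu], collapse = ", "))
  classes <- rep(need, times = class_counts[need])
  structure(list(
    n_ecotypes = as.integer(n_ecotypes), n_blocks = as.integer(n_blocks),
    traits = traits, classes = classes,
    class_multipliers = class_multipliers[need], seed = as.integer(seed)
  ), class = "trial_config")
}

.default_class_counts <- function(n) {
  t <- round(n * 10 / 35); s <- round(n * 12 / 35)
  c(tolerant = t, moderate = n - t - s, sensitive = s)
}

.link_fun <- function(link, kind) {
  if (link == "logit") {
    scale <- if (kind == "percentage") 100 else 1
    list(to = function(x) stats::qlogis(x / scale),
         from = function(e) scale * stats::plogis(e))
  } else {
    list(to = log, from = exp)
  }
}

#' Simulate a split-plot drought trial with known ground truth
#'
#' On each trait's link scale (log for positive/count traits, logit for
#' proportions and percentages, so back-transformed values always respect
#' the trait domain) the model is additive:
#' `eta = link(mu_WS) + block_i + wholeplot_ij + ecotype_k +
#' I(WD) * multiplier_k * delta + resid`, where `delta` is the link-scale
#' shift that takes `mu_WS` to `mu_WS * (1 + drought_effect)` and
#' `multiplier_k` is the ecotype's tolerance-class multiplier (the
#' regime-by-ecotype interaction). Count traits are rounded to integers.
#' Every trait draws from its own random stream keyed on the trait name and
#' the master seed, so identical `(config, seed)` give identical data and
#' adding a trait leaves the others' draws untouched.
#'
#' @param config a [trial_config()].
#' @return a list with `observations` (long tibble: ecotype, water_regime,
#'   block, trait, value) and `ground_truth` (list: `classes` tibble with
#'   the latent class, multiplier and, when DMY is simulated, the noise-free
#'   expected yields `Ys_true`/`Yp_true`; `effects` with every realized
#'   random-effect draw per trait).
#' @examples
#' trial <- simulate_trial(trial_config(n_ecotypes = 4, n_blocks = 2, seed = 42))
#' head(trial$observations)
#' trial$ground_truth$classes
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  g <- config$n_ecotypes; b <- config$n_blocks
  ecotypes <- sprintf("E%02d", seq_len(g))
  mult <- unname(config$class_multipliers[config$classes])
  regimes <- c("WS", "WD")
  grid <- expand.grid(block = seq_len(b), water_regime = regimes,
                      ecotype_i = seq_len(g), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)

  obs_list <- vector("list", nrow(config$traits))
  effects <- list()
  truth_yield <- NULL
  for (t in seq_len(nrow(config$traits))) {
    p <- config$traits[t, ]
    lk <- .link_fun(p$link, p$kind)
    eta0 <- lk$to(p$mu_WS)
    delta <- lk$to(p$mu_WS * (1 + p$drought_effect)) - eta0
    set.seed(sub_seed(config$seed, paste0("trait:", p$trait)))
    eff <- list(
      block = stats::rnorm(b, 0, p$sigma_block),
      wholeplot = matrix(stats::rnorm(b * 2L, 0, p$sigma_wholeplot), b, 2L,
                         dimnames = list(NULL, regimes)),
      ecotype = stats::rnorm(g, 0, p$sigma_ecotype),
      resid = stats::rnorm(nrow(grid), 0, p$sigma_resid)
    )
    effects[[p$trait]] <- eff
    wd <- grid$water_regime == "WD"
    eta <- eta0 +
      eff$block[grid$block] +
      eff$wholeplot[cbind(grid$block, match(grid$water_regime, regimes))] +
      eff$ecotype[grid$ecotype_i] +
      ifelse(wd, mult[grid$ecotype_i] * delta, 0) +
      eff$resid
    value <- lk$from(eta)
    if (p$kind == "count") value <- pmax(round(value), 0)
    obs_list[[t]] <- tibble::tibble(
      ecotype = ecotypes[grid$ecotype_i], water_regime = grid$water_regime,
      block = grid$block, trait = p$trait, value = value
    )
    if (p$trait == "DMY") {
      truth_yield <- tibble::tibble(
        ecotype = ecotypes,
        Yp_true = lk$from(eta0 + eff$ecotype),
        Ys_true = lk$from(eta0 + eff$ecotype + mult * delta)
      )
    }
  }
  classes <- tibble::tibble(ecotype = ecotypes, class = config$classes,
                            multiplier = mult)
  if (!is.null(truth_yield))
    classes <- dplyr::left_join(classes, truth_yield, by = "ecotype")
  list(observations = dplyr::bind_rows(obs_list),
       ground_truth = list(classes = classes, effects = effects,
                           seed = config$seed))
}

#' Simulate leaf water-status samples with a target relative water content
#'
#' Generates (FWT, TW, DW) weight triples whose implied relative water
#' content equals the target up to optional Gaussian noise on the fresh
#' weight: `FWT = DW + (TW - DW) * target / 100`. Noisy fresh weights are
#' clamped to the feasible interval `[DW, TW]`, so `TW >= FWT >= DW > 0`
#' always holds.
#'
#' @param target_rwc vector of target RWC values in \[0, 100\].
#' @param tw,dw turgid and dry weights (g), recycled; `tw > dw > 0`.
#' @param noise_sd standard deviation of the fresh-weight noise (g).
#' @param seed optional seed for the noise stream.
#' @return a tibble with `FWT`, `TW`, `DW` and the implied `RWC`.
#' @examples
#' simulate_leaf_rwc_samples(50, tw = 10, dw = 2)  # FWT = 6
#' @export
simulate_leaf_rwc_samples <- function(target_rwc, tw = 10, dw = 2,
                                      noise_sd = 0, seed = NULL) {
  if (any(target_rwc < 0 | target_rwc > 100))
    stop_input("target RWC must lie in [0, 100]")
  n <- max(length(target_rwc), length(tw), length(dw))
  target_rwc <- rep_len(target_rwc, n); tw <- rep_len(tw, n); dw <- rep_len(dw, n)
  if (any(dw <= 0) || any(tw <= dw)) stop_input("need tw > dw > 0")
  fwt <- dw + (tw - dw) * target_rwc / 100
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(sub_seed(seed, "rwc-noise"))
    fwt <- pmin(pmax(fwt + stats::rnorm(n, 0, noise_sd), dw), tw)
  }
  tibble::tibble(FWT = fwt, TW = tw, DW = dw,
                 RWC = relative_water_content(fwt, tw, dw))
}

#' Per-ecotype yield pairs from trial observations
#'
#' Averages the yield trait over blocks within each regime to give the
#' stress (`Ys`, WD) and non-stress (`Yp`, WS) yields that the
#' drought-tolerance indices are computed on.
#'
#' @param observations a long observation tibble containing the yield trait.
#' @param trait yield trait name (default `"DMY"`).
#' @return a tibble with `ecotype`, `Ys`, `Yp`.
#' @export
yield_pairs <- function(observations, trait = "DMY") {
  d <- observations[observations$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop_input("no observations for yield trait ", trait)
  d |>
    dplyr::group_by(.data$ecotype, .data$water_regime) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "water_regime", values_from = "mean") |>
    dplyr::transmute(.data$ecotype, Ys = .data$WD, Yp = .data$WS)
}
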