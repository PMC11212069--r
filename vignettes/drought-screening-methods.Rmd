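---
title: "Methods: drought-tolerance screening of split-plot forage trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-tolerance screening of split-plot forage trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

## The experiment being analysed

A drought screen compares a panel of G genotypes (here: forage grass
ecotypes) under two irrigation regimes — water-sufficient (WS) and
water-deficit (WD) — in a randomized complete block design with a
**split-plot arrangement**: within each of b blocks, each regime is applied
to one whole plot, and every ecotype occupies one sub-plot inside each whole
plot. Irrigation cannot be randomized at the pot level, so the regime is the
main-plot factor and the ecotype the sub-plot factor; this is the standard
assignment for irrigation trials and the one this package hard-codes.

Eleven traits are supported: plant height (PH, cm), tiller number (NT),
leaf number (NL), root length (RL, cm), shoot fresh weight (FWT, g), dry
matter yield (DMY, g/plant), relative water content (RWC, %), photosystem-II
photochemistry (Phi2), non-photochemical quenching (PhiNPQ), relative
chlorophyll content (SPAD) and maximum PSII efficiency (Fv/Fm). Each trait
carries a domain (counts ≥ 0, proportions in [0, 1], percentages in
[0, 100]) that validation enforces on input and the generator preserves on
output.

## Split-plot analysis of variance

For a balanced trial the decomposition is closed-form. With y_ijk the
observation in block i, regime j, ecotype k:

* SS(block), SS(regime), SS(error a) = SS(block × regime) — the whole-plot
  stratum;
* SS(ecotype), SS(regime × ecotype), SS(error b) = remainder — the sub-plot
  stratum.

The regime F statistic uses MS(error a) as its denominator; ecotype and
interaction use MS(error b). Degrees of freedom and sums of squares are
exactly additive, which the test suite asserts on random balanced designs;
the implementation is cross-checked against `aov()` with an `Error()`
stratum, which serves only as an independent oracle. Unbalanced data are a
fatal error that lists the missing cells — no approximate decomposition is
attempted (and no REML mixed model is offered; that is out of scope).

**LSD and CV% are per regime.** Published screening tables print one LSD and
one CV per regime column, which a single pooled sub-plot error cannot
produce; both are therefore computed from the residual mean square of a
within-regime randomized-complete-block fit (block + ecotype):
LSD = t(1 − α/2, df_e) · √(2·MS_e/b), CV% = √MS_e / ȳ × 100. Letter codes
use the standard sweep over means in descending order: ecotypes share a
letter iff their means differ by at most the LSD. The LSD procedure makes no
multiplicity correction beyond its own design; this is anti-conservative for
35 ecotypes and users who need familywise control should treat the letters
as descriptive.

Degenerate inputs: all-constant data give zero SS everywhere and the F
statistics are omitted with a warning rather than reported as 0/0.

## Stress responses

The stress response of a trait is the signed percent change of the WD mean
relative to the WS mean. `response_table()` reports one row per
ecotype × trait and an `ALL` row per trait from grand means. When the input
is one of the packaged published tables, the `ALL` row uses the table's own
printed grand-mean footer at its printed precision rather than re-averaging
the per-ecotype means: the published headline percentages (e.g. Phi2
−50.0 %) are computed from the printed grand means (0.36 → 0.18), and
re-derived averages differ in the second decimal (−49.4 %), which would be a
spurious disagreement with the source. For data without a printed footer the
grand mean is the arithmetic mean of ecotype means.

## Drought-tolerance indices

For per-ecotype mean yields Ys (WD) and Yp (WS) with cohort means Ȳs, Ȳp:
MP = (Ys+Yp)/2, GMP = √(Ys·Yp), TOL = Yp−Ys, YSI = Ys/Yp, YI = Ys/Ȳs,
SSI = (1−Ys/Yp)/(1−Ȳs/Ȳp), STI = Ys·Yp/Ȳp². Exact identities follow from
the formulas and are asserted as tests: mean(YI) = 1, GMP ≤ MP with equality
iff Ys = Yp, Σ STI · Ȳp² = Σ Ys·Yp, and unit invariance of YSI, YI, SSI,
STI under rescaling of all yields. SSI is undefined for a cohort with
Ȳs = Ȳp (a no-stress trial) and is returned as NA with a warning.

Ranking direction is encoded per index: larger is more tolerant/productive
for MP, GMP, YI, STI, YSI and the raw yields; smaller is better for SSI and
TOL. The explicit metadata prevents the silent misranking that TOL invites
(it is both "useful for selection" and a loss measure). Ties break by
ecotype identifier, making every ranking reproducible.

## PCA ranking and clustering

Traits are z-scored before decomposition — RL (~50 cm) would otherwise
dominate Fv/Fm (~0.2). Component contributions are 100·λ_m/Σλ. Because an
eigenvector's sign is arbitrary, a deterministic convention is applied (the
largest-magnitude loading in each component is made positive) so repeated
runs are identical.

The genotype ranking value is RV_g = Σ_m contribution_m(%) · score_gm over
the first four components, with contributions entering as percentages (not
proportions): that is the only reading compatible with published ranking
values of magnitude ~±160 for scores of magnitude ~±4. A dense rank 1..G by
descending RV classifies the panel (top ≈ tolerant, bottom ≈ sensitive).

Two caveats are documented rather than resolved. First, the packaged
published ranking table prints the per-ecotype scores and ranking values but
not the four contribution percentages, so the ranking values cannot be
recomputed from the scores; the package asserts their internal
rank-consistency (sorting the printed values descending reproduces the
printed ranks 1..35 exactly) and applies the same contract to every computed
ranking. Second, a PCA of the nine-trait ecotype-mean matrix available in
the packaged tables need not reproduce the published scores: the published
analysis included FWT and DMY, whose per-ecotype values are not printed, and
may have used replicate-level data. The packaged cluster partition likewise
records one stated share (37.1 % for an 8-member cluster of 35) that is
arithmetically inconsistent with its own size listing; the fixture stores
the sizes as printed and the profiling operation computes shares from sizes
(8/35 = 22.9 %), with the discrepancy kept as a fixture note.

Clustering is agglomerative on Euclidean distances of the z-scored profiles;
Ward (D2) is the default linkage — the usual choice for compact trait-based
groups — with average and complete selectable, since the source analyses of
this kind typically name only the distance. Cluster profiles report means ±
SEM on the original trait scale.

## The synthetic trial generator

`simulate_trial()` exists so every downstream stage can be validated against
a known truth. On each trait's link scale (log for positive and count
traits, logit for proportions/percentages) the model is the additive
split-plot model:

```
eta_ijk = link(mu_WS) + block_i + wholeplot_ij + ecotype_k
          + I(j = WD) · m_k · delta + eps_ijk
```

where delta is the link-scale shift taking mu_WS to
mu_WS·(1 + drought_effect), and m_k is the ecotype's tolerance-class
multiplier — the regime × ecotype interaction. Working on the link scale
keeps back-transformed values inside the trait domain for any noise draw;
counts are rounded. With all sigmas zero and unit multipliers the WD value
is exactly mu_WS·(1 + drought_effect), which the tests exploit as a closed
form. Each trait draws from its own random stream keyed on the trait name,
so extending a configuration never perturbs existing traits, and identical
(config, seed) reproduce the dataset bit for bit.

**Calibration.** Per-trait `mu_WS` and `drought_effect` equal the grand-mean
rows and grand percent changes of the packaged tables (PhiNPQ is the one
trait with a positive effect, +28.3 %); residual sigmas follow the printed
CV% rows (e.g. PH ~37 % on the log scale); block and whole-plot sigmas are
set to a small 0.05 (no published anchor exists — variance components are
not reported for trials of this kind). Class multipliers default to
tolerant 0.45 / moderate 1.0 / sensitive 1.6, spanning expected WD yields of
roughly 2.5 / 1.4 / 0.7 g/plant, matching the ~3× spread of published
per-cluster WD yields; the within-class ecotype sigma for DMY is 0.05 log
units, i.e. the class structure carries most of the between-ecotype yield
variance. Under these defaults the generator is a usable benchmark: STI
ranking recovers ≥ 8 of the 10 planted tolerant ecotypes in ~93–95 % of
seeded trials, and with ecotype and interaction effects switched off the
split-plot ecotype F-test holds its nominal 5 % size.

**What it does not emulate.** No dry-down dynamics or soil-moisture time
series — the regime contrast is a fixed shift; no trait–trait residual
correlation within a plant; Gaussian errors on the link scale are an
assumption, not an estimate. One consequence worth knowing: correlation
structure among the yield indices depends on which variance source
dominates. Under the defaults (class-dominated), TOL correlates negatively
with Ys; in cohorts whose intrinsic productivity varies widely
(`sigma_ecotype` ≈ 0.5 for DMY) the classical pattern emerges — MP, GMP,
TOL, STI, YI all positive with both yields, YSI against SSI — and that is
the regime real panels are typically in. Tests exercise both regimes
deliberately. Passing tests on synthetic data show the machinery is correct
under the stated model, not that real trials satisfy the model.

## Numerical conventions and problem sizes

* Percent changes are computed from means at their printed precision when a
  printed footer exists; reporting rounds to one decimal, round-half-even.
* Missing cells in a trait matrix drop the affected row with a warning —
  never imputation.
* The published-table fixtures are transcribed verbatim as UTF-8 CSV; four
  typographic defects in the source (a run-together `6.20.37` token and
  three dropped decimal points in SEMs) are repaired with the parse recorded
  in `fixture_notes.json`, and two printed grand-mean cells that disagree
  with their own columns by about one unit in the last digit are asserted
  with a documented slop instead.
* Monte-Carlo checks use 1,000 trials for the ANOVA test size (binomial SE
  ≈ 0.7 %) and 200 seeded trials for STI recovery; the eigenvalue oracle
  runs on 10 × 6 matrices. These sizes give stable verdicts at interactive
  runtimes.
* All tie-breaks (ranking, letter groups) are by identifier; all randomness
  descends from one master seed via per-stream hashes below 2^31.
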