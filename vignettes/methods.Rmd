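---
title: "Models and methods behind myxofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myxofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxofit)
```

## The measurement chain

A developmental competition assay produces one observable: colony counts on
agar plates poured from dilutions of a harvested spore sample. `myxofit`
models the chain from that observable to qualitative social-fitness calls in
four stages, each a separate module with its own contract.

**1. Counts.** One row per plate: the spot it came from (pair or pure
culture, the nutrient history of each partner, the replicate), the selection
(non-selective or a marker agar), the dilution as a fraction, the plated
volume and the harvest volume. The plated fraction — the share of the whole
harvested sample represented on the plate — is always derived as
`volume x dilution / harvest volume`, never supplied, which makes it
invariant to how the bookkeeping scales volumes. Plates too dense to count
are recorded as uncountable lawns and excluded from estimation rather than
guessed.

**2. Spore totals.** All countable plates of one (spot, selection) sample
are pooled with the Poisson maximum-likelihood estimator
`N = sum(colonies) / sum(plated fraction)`. This is the natural choice: with
counts `c_k ~ Poisson(N f_k)` the likelihood in `N` is maximised exactly
there, it reduces to `colonies / fraction` for a single plate, and it is
invariant to splitting or merging plates. A sample whose countable plates
are all colony-free sits at the lower limit of detection and is imputed at
0.9 spores — below one colony-equivalent, but positive, so every downstream
log-ratio stays finite; the imputation is applied once per pooled sample,
not per plate, and carries a flag. Mixed cultures are deconvolved by the
design's counting scheme: marked strains take their marker-plate estimates,
and at most one unmarked strain per pair is estimated by subtraction from
the non-selective total. A subtraction that comes out non-positive (possible
under counting noise when the marked strain dominates) is clamped to the
same 0.9 floor and flagged, never propagated as zero or negative; a strict
mode turns the clamp into an error.

**3. Fitness statistics.** With `D = spores / initial cells` the sporulation
efficiency, the two social statistics are `W_ij = log10 D_i(j) - log10
D_j(i)` (relative fitness within a mix; antisymmetric by construction) and
`C_i(j) = log10 D_i(j) - log10 D_i` (mixing effect versus the pure culture
of the focal strain grown under the *same* nutrient history). Initial cells
come from the design constants: 0.1 ml spotted at 5e9 cells/ml gives 5e8
cells per spot, split 2.5e8/2.5e8 in 1:1 mixes and 5e7/4.5e8 in 1:9 mixes.
The pure-culture reference for C is taken from the same replicate when it
exists — replicates are temporally separate experiments, so pairing within
replicate removes day effects — and otherwise falls back to the
cross-replicate geometric mean (mean on the log10 scale, consistent with the
statistic), flagged `pure_ref = "mean"`. Detection-limit involvement
propagates as flags rather than censoring: the strongest suppression
outcomes are precisely the ones at the detection floor, and censoring them
would bias every downstream call toward "no effect".

**4. Inference and calls.** Two questions are asked per (pair, statistic)
family: (a) is the statistic different from zero in each history cell
(two-sided one-sample t, Bonferroni-Holm over the four cells of the family);
(b) does nutrient history affect the interaction (Tukey HSD over all cells,
and Dunnett contrasts against the H/H standard-condition reference). The
factorial ANOVA is a Gaussian linear model with identity link — the
responses are continuous log-scale statistics, which is what an F-table
implies — crossing genotype with each partner's nutrient history; on the
balanced design, sequential and Type III sums of squares coincide, so term
order is immaterial. Verdicts per cell follow sign-and-significance rules:
`+` for a significantly positive mean, `antagonized` for a significantly
negative one, `-` otherwise, and a `+` cell whose Dunnett contrast shows a
significant decrease from H/H becomes `reduced-but-present`.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.05 | — | conventional family-wise level; all tests two-sided, direction read from the mean |
| Holm family | 4 history cells of one (pair, statistic) | — | the natural unit of one question about one pair; recorded in the output provenance |
| `log_base` (C) | 10 | — | consistency with the explicit base-10 of W; all sign-based conclusions are base-invariant |
| `lod_spores` | 0.9 | spores | limit-of-detection imputation, also the subtraction clamp floor |
| `density_cells_per_ml` | 5e9 | cells/ml | resuspension density of the assay |
| `spot_volume_ml` | 0.1 | ml | spotted volume, giving 5e8 cells per spot |

Tukey and Dunnett assume equal variances across cells (the standard pooled
implementations). Dunnett's single-step adjusted p-values involve a
multivariate-t integral evaluated by quasi-Monte-Carlo; the integration runs
under a locally fixed RNG state (saved and restored), so pipeline output is
byte-identical across runs and never perturbs the caller's random stream.
Holm ties are handled in a stable label order.

## The synthetic-experiment generator

`generate_experiment()` emulates the assay end to end so every stage is
testable with known truth. Per treatment and replicate, each strain's latent
log10 sporulation efficiency is

    base(strain, own history) + delta(pair, focal, history cell) + N(0, sigma_rep)

with the interaction delta applying only in mixes. Spores are
`initial cells x 10^latent`, and each plate's colonies are
`Poisson(spores x plated fraction)`. Because deltas act additively on log10
efficiency, the truth is closed-form: `true W = latent_a - latent_b` and
`true C_i = delta_i`, with no sampling. Two invariants anchor the test
suite: full mode is byte-identical under a fixed seed, and expectation mode
(sigma and Poisson disabled, plates carry exact real-valued expected counts)
must be recovered by the pipeline to within floating-point tolerance
whenever no detection-limit clamp fires.

Defaults are chosen as study-like conditions: 4 temporally separate
replicates; pure-culture baselines independent of nutrient history (the
empirical single-genotype pattern — history effects live entirely in the
interaction deltas); `sigma_rep = 0.2` log10 units as a realistic
between-replicate spread for spore counts (the value is a modelling choice,
not an empirical claim); duplicate pour plates per dilution with counts up
to 1000 colonies treated as countable (colonies embedded in poured agar stay
countable at higher density than surface-spread ones).

**Preset scenarios.** `preset_paper_like("cheater_pairs")` encodes two
obligate defectors (pure-culture log10 efficiency -7, i.e. tens of spores
per 5e8-cell spot, so the pure-culture detection-limit path is exercised)
mixed 1:9 with a cooperator (log10 efficiency -2). The deltas encode
cheating wherever the scenario intends it: pair 1 cheats whenever the
cooperator grew at high resources; pair 2 cheats everywhere except L/L, with
its L/H cell weaker than H/H. `preset_paper_like("natural_isolates")`
encodes three cooperation-proficient isolates mixed 1:1 with a strongly
suppressed partner (delta -5, spore share < 0.01%) and history-dependent
exploitation by the dominant strains.

**Power calibration of the cheater preset.** The preset's purpose is a
recoverable qualitative grid, so its effect sizes were set by an explicit
power computation rather than aesthetics. With n = 4 and
`sigma_rep = 0.2`, a replicate W value has SD near `sqrt(2) x 0.2 = 0.28`,
and the weakest positive cell must survive a Holm factor of 2, i.e. raw
p < 0.025 on 3 degrees of freedom (critical t = 4.18). A noncentral-t
computation then gives per-cell miss rates of about 11% at W = +0.8, 2% at
W = +1.2 and 0.2% at W = +1.5; the preset therefore uses +1.5 for strong
cheating (a ~32-fold per-capita advantage) and +1.2 for the reduced cell.
The plating model matters just as much: with sparse counts, the
subtraction-counted cooperator (a minority of the mix once the cheater
dominates) can overshoot and clamp, producing flagged outlier W values that
wreck a cell's t test. The half-decade dilution series guarantees every
sample a near-saturated countable plate, keeping pooled relative counting
error around 2% and making clamps vanishingly rare. The residual
reduced-versus-H/H Dunnett flag has limited power under full noise (the gap
is 0.3 log10 against a contrast SE of about 0.2) — it is verified exactly in
expectation mode instead.

**Degenerate tests in expectation mode.** Noise-free data make all four
replicates identical, so a one-sample t statistic has zero denominator.
These cases are reported as degenerate with no p-value, but a constant value
different from the null is flagged significant — with zero sampling
variance, the sign is exact — which is what makes the expectation-mode
outcome grid a well-defined oracle. Dunnett contrasts degenerate the same
way (zero residual variance; significance by exact nonzero estimate).

## Problem sizes used by the test suite

The simulation-based checks are sized to be decisive yet quick: 10,000
Poisson draws for estimator unbiasedness (relative bias under 1% at expected
counts of 20+ per plate); 500 simulated null experiments for type-I control
of the `+` calls (bounded by 0.05 plus three Monte-Carlo standard errors
over 2000 cells); 60 full-noise preset experiments for qualitative grid
recovery (threshold 90%); brute-force Holm enumeration over all family
sizes up to 6.

## Known limitations

* **No overdispersion.** Plating noise is pure Poisson on top of a
  log-normal replicate effect; real colony counts can be overdispersed
  (pipetting, clumping). The replicate-level SD absorbs much of this, but a
  per-plate overdispersion term would be the next refinement.
* **Subtraction-counted strains inherit the total's noise.** When the
  marked partner dominates a mix, the unmarked strain's estimate is a small
  difference of large numbers; the pipeline clamps and flags impossible
  values but does not model the resulting heavy-tailed error.
* **Equal-variance contrasts.** Tukey/Dunnett pool variance across cells;
  cells at the detection floor can have very different spread. A Welch-style
  fallback would relax this at the cost of non-standard Dunnett quantiles.
* **Single developmental episode.** No population dynamics across cycles,
  no mechanistic model of developmental timing, signalling or lysis; the
  generator reproduces the statistical structure of the assay, not its
  biology, so passing tests validate the analysis chain, not any mechanism.
* **C requires matching-history pure cultures.** Strains without one are
  excluded from mixing-effect analysis (reported, not guessed).
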