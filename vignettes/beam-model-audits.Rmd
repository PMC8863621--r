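---
title: "Auditing TPS beam-model parameters against community practice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing TPS beam-model parameters against community practice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamaudit)
library(dplyr)
```

## The problem

End-to-end dosimetry audits irradiate an anthropomorphic phantom with an
institution's own clinical process and compare measured point doses (TLDs)
and film planes against the institution's treatment-planning-system (TPS)
calculation. A persistent minority of audits fail, predominantly through
*systematic* dose errors: the whole distribution is right-shaped but wrong in
magnitude. One identifiable driver is beam modeling: TPS parameters such as
the Eclipse dosimetric leaf gap (DLG) or the RayStation MLC position offset
are tuned per machine at commissioning, and institutions modeling the *same*
linac class diverge substantially in the values they choose.

`beamaudit` implements the audit-side analysis of that hypothesis:

1. score an institution's reported parameters as percentiles of the
   community distribution within its equipment stratum (same TPS, linac
   class, beam energy, MLC model), flagging the outer 20% — below the 10th
   or above the 90th percentile — as *atypical*;
2. predict the systematic dose-calculation error each parameter value
   induces via a piecewise-linear per-parameter response anchored at
   published community quantiles, and sum the (independent) per-parameter
   effects into one predicted TPS error per institution;
3. classify each phantom audit as failing (any TLD error beyond ±7%, or
   film gamma pass rate below 85%) or poor (any TLD beyond ±5%), excluding
   audits with a film-detected localization offset above 3 mm from
   dose-error estimation;
4. test the association between atypical modeling and audit outcome
   (chi-square overall, Fisher's exact per parameter) and correlate the
   predicted against the observed dose error.

Because the audit database behind the original analysis is proprietary, the
package ships a first-class synthetic-study generator with the same
statistical structure, so every stage is testable end to end.

## The dose-effect model

For each parameter the catalog stores anchors at the community's 2.5th,
10th, 50th, 90th and 97.5th percentiles: the parameter value at that
percentile and the systematic dose effect (in % of dose, relative to the
community-median beam model) that value produces in a head-and-neck IMRT
plan. Phantom recalculations established two empirical facts this model
leans on: dose responds *linearly* to each parameter value over the
community range, and parameter effects are *independent* of one another.
Accordingly:

- `effect_at_value()` interpolates linearly **in parameter value** between
  adjacent anchors and clamps to the terminal anchor effects outside the
  2.5th–97.5th range (effects are characterized only over the reported
  community spread; extrapolating a fitted line beyond it would assert
  physics nobody measured);
- `aggregate_error()` sums per-parameter effects exactly; the empty
  aggregate is 0 and duplicated parameters are an error;
- positive effect means the TPS *overestimates* dose (calculated exceeds
  delivered).

Two details are configuration rather than data. First, published anchor
tables print the median's dose effect (0, definitionally) but not the median
parameter value, so the shipped catalog carries a configured
`median_value`, computed once as the zero-crossing of the straight line
through the 10th/90th (value, effect) anchors — the choice that keeps the
whole 10th–90th span a single line, i.e. the weakest addition consistent
with the linearity finding. (Where both those effects are 0 the midpoint of
the two values is used; where only one is 0, that anchor's value.) An
override file can replace these with measured survey medians. Second,
degenerate segments — equal parameter values at adjacent percentiles, as
with the RayStation MLC transmission's identical 90th/97.5th values —
collapse to one node carrying the lower-percentile effect.

## Percentile scoring

`percentile_of()` inverts the linear-interpolation ("type-7") sample
quantile, the ubiquitous default convention; the forward and inverse
directions therefore round-trip exactly on quantile grids, which is also
what makes anchor-matched synthetic communities score their anchors at the
printed percentiles. Ties take the midrank; values outside the sample range
score 0 or 100. Atypicality cuts are strict (`< 10`, `> 90`), so a value
exactly at a cut is typical. Strata are matched exactly on all four
equipment fields (case- and whitespace-insensitive); there is no fallback
to pooled distributions, and strata with fewer than `min_sample_size = 5`
responses are refused — percentiles from tiny samples are noise presented
as precision. Parameters reported by an institution but absent from the
catalog pass through unscored with a warning.

## Audit outcomes

TLD error is `100 * (calculated - measured) / measured`: the denominator is
the delivered dose, matching the "TPS over/underestimates" reading. The
film comparison uses a global gamma index: dose tolerance expressed as a
percentage of the calculated grid's maximum, a 20% low-dose threshold, and
a discrete search over grid points within 3×DTA (no subpixel
interpolation — deterministic and adequate at the ≤ 1 mm spacings generated
here). Audit exports usually carry a precomputed film pass rate; the
classifier accepts that column directly, and `gamma_pass_rate()` handles
raw 1-D profiles or 2-D planes when they exist. The failing criterion can
be restricted to TLD-only (`use_film = FALSE`), since association analyses
can reasonably be run under either reading. Localization exclusion is
strict at 3 mm.

## The synthetic study generator

`community_model()` turns the anchor (percentile, value) pairs into an
inverse CDF, piecewise linear between anchors and flat beyond the
2.5th/97.5th — again the weakest assumption consistent with the published
quantiles. Institutions draw values by inverse-CDF sampling; an optional
Gaussian copula on ranks induces inter-parameter correlation (the
DLG–transmission coupling observed in practice) without asserting a joint
family. `simulate_audits()` mirrors the estimator's own assumptions
generatively: the true systematic error is the additive aggregate of the
drawn parameters' effects plus `N(0, sigma_residual_pct)` for non-TPS error
modes; each TLD reads nominal 2 Gy with `tld_noise_pct` measurement noise,
and localization offsets are drawn independently of dose error. One master
seed drives deterministic per-institution substreams.

Defaults emulate the study cohort's shape: 337 institutions, phantom mix
258:34:45 (head-and-neck : spine : prostate), gross-localization
probability 11/337 with offsets in 3–10 mm, 8 TLDs per phantom, 1% TLD
noise. The residual-error SD is genuinely unknown; the default
`sigma_residual_pct = 2` is chosen once as a plausible magnitude for the
non-TPS modes (beam data, calibration, delivery) that leaves predicted
errors correlated with, but far from identical to, measured ones —
qualitatively matching the estimated-vs-true scatter such audits show. It
asserts nothing about the real dispersion.

What passing synthetic tests do **not** show: real communities have tails
beyond the anchors and survey medians need not sit at the interpolated zero
crossing; real audits include TPSs without characterized anchors, non-Gaussian
error modes and correlated residuals; and the generator's linear/independent
effects are the estimator's own assumptions, so closure tests certify the
pipeline's internal consistency, not the physics.

## Numerical and statistical choices

- Fisher's exact p-value is two-sided by probability-mass ordering (the
  standard software convention; the hypotheses are two-sided), computed via
  `stats::fisher.test` and verified in the test suite against an
  independent hypergeometric enumeration on every 2×2 table with total
  ≤ 30. The reported odds ratio is the sample `ad/bc` (degenerate cells
  flagged), not the conditional MLE.
- Chi-square is Pearson's without continuity correction by default
  (available by flag); zero expected counts are an error.
- Raw per-test p-values are reported, matching the original analysis; a
  Benjamini–Hochberg column is added within the per-parameter family for
  transparency only.
- Tests with fewer than 3 usable records or a degenerate margin are
  reported as not-computed rows, never errors — a cohort slice being too
  small is a result, not a crash.
- All thresholds (7%/5% TLD, 85% film, 10/90 cuts, 1% impact, 3 mm
  localization) are arguments of `run_audit_analysis()` with the audit
  program's values as defaults; nothing is hard-coded in stage logic.

## Known limitations

- Anchor-implied communities place point masses at the terminal anchor
  values (the flat inverse-CDF extensions). Midrank scoring keeps the
  outer-20% calibration intact when those atoms sit outside the cuts, but a
  parameter whose configured median coincides with its 10th-percentile
  value (e.g. an MLC curvature community where most users leave 0) has a
  large atom *spanning* the low cut, and its low tail can then never be
  flagged — a property of the published quantile structure, not a bug in
  scoring.
- The percentile route to a dose effect depends on the supplied
  distribution's quantiles; with a survey whose quantiles deviate from the
  anchor values the value route (`effect_at_value()`) and the percentile
  route legitimately disagree.
- Problem sizes in the test suite (cohorts of 25–600 institutions; 100–500
  simulation replicates; 2,000-draw calibration samples) are the package's
  own choices balancing Monte-Carlo error against runtime.

## A worked example

```{r example, eval = FALSE}
anchors <- load_anchors()
cm <- community_model(anchors, "Eclipse AAA")
cfg <- cohort_config(n_institutions = 120, seed = 42)
study <- generate_study(cm, cfg)

res <- run_audit_analysis(study$survey, study$audit, truth = study$truth)
glance(res)          # cohort rates and the estimated-vs-true r
tidy(res)            # the full association table
autoplot(res)        # predicted vs true systematic error
```
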