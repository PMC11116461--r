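---
title: "Modelling the ontogeny of dental enamel stress markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ontogeny of dental enamel stress markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Enamel hypoplasia is a localized deficit of enamel thickness left behind
when a physiological disruption — illness, malnutrition, weaning stress —
interrupts crown formation. Because enamel does not remodel, the vertical
position of a defect within a tooth crown is a permanent record of *when*
in childhood the disruption happened. `lehstress` implements a complete
analysis chain for comparing the frequency and ontogenetic timing of
such growth disruptions between two Paleolithic hominin groups,
Neanderthals (NEA) and Upper Paleolithic modern humans (UPMH), from
tooth-level scoring data:

1. tooth-specimen and defect-observation tables with validation and a
   preservation-based inclusion filter;
2. a deterministic 11-stage crown-formation staging system and matched
   systemic-stress-episode detection;
3. two Bayesian hierarchical Bernoulli models with a built-in no-U-turn
   sampler, convergence gates, odds-ratio contrasts, fitted stage curves
   and finite-difference change-period detection;
4. a seeded synthetic cohort generator with known ground truth used for
   all calibration and recovery testing.

## Data model and inclusion rule

A `ToothSpecimen` records one scored crown: specimen, individual and
site identifiers, taxon, tooth class (`I1`, `I2`, `C`, `P3`, `P4`,
`M1`, `M2`, `M3`, or the pooled `DECIDUOUS` category), jaw, the
preserved fraction of crown height, and a boolean summarizing surface
condition. A `DefectObservation` records one hypoplastic defect: its
form (`FURROW` — linear enamel hypoplasia, `PIT`, or `LHPC`, the
deciduous-canine-specific form) and the crown vertical third it sits in,
indexed in formation order (1 = incisal/occlusal, 3 = cervical).
Indexing thirds in formation order makes the staging map monotone in
developmental time.

`filter_included()` retains exactly the specimens with at least 50% of
crown height preserved and surfaces in good condition. The rule is "at
least", so a fraction of exactly 0.5 is retained. Side (left/right) is
not modelled anywhere: tooth types are pooled across side and jaw in the
tooth-level model, and only jaw (for incisors) affects staging.

## The staging system

Stages are defined by which crown thirds of which tooth types form
concurrently in the reference (modern Northern European) schedule.
Stage 1 pools the deciduous dentition; stages 2–8 span permanent crown
formation from incisor initiation to second-molar completion; stage 9 is
the *formation hiatus* between M2 completion and M3 initiation — no
crown third ever maps to it, but it is kept in the stage scale because
the smooth model needs the gap to be explicit; stages 10–11 cover the
third molar. Jaw matters only for incisors (upper and lower incisors
complete their thirds at different stages); canines map to stages
{3, 4, 6} with no presence at stage 5, exactly as the schedule has it —
no interpolation across the gap.

Episode matching implements the contemporaneity rule: furrow-form
defects on **two or more** teeth of one individual assigned to the same
stage are one systemic stress episode at that (individual, stage). Pits
and LHPC are never matched. Design choices the source protocol leaves
open, decided here once:

* *One episode per (individual, stage)*, however many teeth support it —
  an episode may be a single event or a series of closely timed events,
  and the per-stage episode bookkeeping implies per-stage aggregation.
* *Antimeres count as distinct specimens* for the ≥ 2 rule; a stricter
  `distinct_classes_only` variant is available as an argument.
* *A defect spanning a third boundary is recorded in the earlier-forming
  third* (data-entry guidance; the schema carries a single third). This
  is conservative about onset timing.
* A stage is *observable* for an individual when at least two of their
  included crowns have some third mapping to it; eligibility for the
  episode-level model requires a non-empty observable set. Observability
  requires only specimen inclusion, not preservation of the specific
  third — a known limitation, noted rather than modelled.

## Model 1: tooth-level defect presence

For tooth $i$ with taxon–by–tooth-category cell $c(i)$, individual
$j(i)$ and site $k(i)$:

$$y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_{c(i)} +
u_{j(i)} + v_{k(i)}))$$

with $y_i = 1$ when the tooth carries at least one defect of any form.
Fixed effects use **cell-means coding** over the 18 cells (2 taxa × 9
categories) because every reported quantity — cell probabilities, taxon
averages, odds ratios — is a cell contrast; the equivalence with
treatment coding plus interaction is a test, not a user option. Priors
are weakly informative: $\beta_c \sim N(0, 1)$,
$u_j \sim N(0, \sigma_{\mathrm{ind}})$,
$v_k \sim N(0, \sigma_{\mathrm{site}})$, and
$\sigma \sim \mathrm{Exponential}(1)$ for every standard deviation.

Reported cell probabilities are population averages: the inverse-logit
of the cell coefficient with random effects at zero. Taxon averages pool
the nine cell logits with equal weights on the link scale and
back-transform (a response-scale option exists). Odds-ratio contrasts
are computed per draw as $\exp(\beta_{\mathrm{NEA},t} -
\beta_{\mathrm{UPMH},t})$ and summarized by the median and the 95%
equal-tailed credible interval; no multiplicity adjustment is applied —
interpretation rests on the degree of overlap of the interval with 1.

## Model 2: individual-level stress episodes across stages

For eligible individuals (at least one furrow defect and at least two
concurrently forming crowns), one row per (individual, stage) carries
the episode indicator. The linear predictor is

$$\eta_{js} = \beta_0 + \alpha_{t(j)} + f_{t(j)}(z(s)) + u_j + v_{k(j)}$$

where $z(s)$ standardizes stage over the emitted rows and $f_t$ is a
per-taxon smooth: a cubic B-spline with 8 basis functions on the
standardized image of the full stage range 1–11, whose coefficients
share a taxon-specific shrinkage prior
$\gamma_{t\ell} \sim N(0, \sigma_{\mathrm{sm},t})$,
$\sigma_{\mathrm{sm},t} \sim \mathrm{Exponential}(1)$ — the
random-effects representation of a penalized spline, which keeps the
stated prior families while penalizing wiggliness. The per-taxon
intercept offsets $\alpha_t \sim N(0,1)$ absorb level differences so the
smooths capture shape. The basis dimension is configurable
(`n_basis`); 8 is the default as the smallest dimension that can track
one peak and two shoulders over 11 stages without visible basis
artifacts.

Two row policies are implemented because the observational protocol does
not pin one down. Under the default `"observable"` policy an individual
contributes rows only for their observable stages, **plus stage 9 as a
structural zero** (the hiatus is kept so the smooth is anchored across
the gap, mirroring why the stage exists at all). Under `"all_stages"`
every individual contributes all 11 rows. The default is the
conservative choice: it never asserts the absence of an episode at a
stage the individual's preserved dentition could not have recorded.

## Sampling and diagnostics

The posterior is sampled with the package's own gradient-based
no-U-turn sampler (multinomial trajectory sampling, dual-averaging step
size targeting acceptance 0.95, windowed diagonal mass-matrix
adaptation, max tree depth 10), written against the exact log-posterior
and its analytic gradient. Random intercepts and spline coefficients are
sampled non-centered ($u = \sigma z$, $z \sim N(0,1)$); this is a
contract-level reparameterization — the posterior is identical, the
funnel geometry is not. Defaults are 4 chains × (1000 warmup + 2000
retained) = 8000 post-warmup draws. A single master seed fans out
deterministically to per-chain (and per-replicate) seeds, so every
result is exactly reproducible.

`diagnose()` gates every parameter on three criteria: split
rank-normalized $\widehat{R} < 1.01$, bulk effective sample size above
10% of the total post-warmup draws, and Monte Carlo standard error
below 5% of the posterior sd. Constant chains raise an explicit
degenerate-chain error rather than a silent NaN. Note the MCSE gate is
equivalent to ESS > 400 regardless of run length, so deliberately
scaled-down calibration fits (2 chains × 500 draws) often fail gates
while still producing well-calibrated intervals; calibration summaries
therefore record gate failures instead of dropping replicates.

Posterior predictive checks simulate replicate response vectors per
(thinned) retained draw at the draw's full linear predictor — including
its sampled random effects — and compare the observed statistic (overall
or per-taxon response proportion) with the replicate distribution via a
two-sided tail probability. Because the statistic is discrete, tails
use the mid-p convention (ties split evenly), which keeps the tail
probability approximately uniform when the data really come from the
model.

## Derivative-based change periods

Periods of marked increase or decrease of the fitted stage curve are
found by central finite differences on the probability scale:
$f'(x) \approx [f(x+h) - f(x-h)] / 2h$ per draw, on a grid of 201
equally spaced points over stages 1–11 with $h = 0.01$ stage units
(derivatives are taken only where $x \pm h$ stays inside the range — no
extrapolation). A grid point is flagged when the 95% CrI of the
derivative excludes zero; contiguous flagged points of common sign merge
into maximal segments. The probability scale is used because the curves
are reported as likelihoods.

## The synthetic cohort generator

No tooth-level data are deposited for the original sample, so the
generator is the package's test bed. Its defaults emulate the study's
declared structure: 74 NEA and 102 UPMH individuals across 56 sites
(site sizes proportional to 1/rank — a few large, many small sites),
and 423 + 444 *included* teeth in expectation. Teeth per individual are
zero-truncated Poisson with per-taxon means solved so that, at the
study-wide preservation pass rate (867/1048), the expected included
counts match the declared ones. Preservation is a Beta(5, 1.5) crown
fraction plus a Bernoulli surface indicator solved from the pass rate.

Defects arise in two layers. Systemic stress events are drawn per
(individual, stage) with probability
$\mathrm{logit}^{-1}(\mathrm{logit}\,\pi_t(s) + u_j + v_k)$; an event
deposits a furrow on the earliest-forming third of every crown forming
at that stage, each with manifestation probability 0.9. This generative
rule is the mirror image of the matching rule, constructed so the
episode analysis is identifiable. Idiosyncratic defects are added per
tooth at baseline logit $\mathrm{qlogis}(0.05)$ shifted by the same
random intercepts, so the tooth-level response is not fully determined
by systemic events. The default stage curves are qualitative shapes,
not fitted values: UPMH rising from stage 1 to a 0.30 peak at stage
3.5 then decaying; NEA rising from stage 3 to a 0.35 peak at stage 6,
zero after stage 8; both zero at the stage-9 hiatus.

What the generator does **not** emulate: taphonomic structure beyond
preservation fractions, within-individual correlation of tooth classes
(real individuals contribute anatomically coherent dentitions),
deciduous subtypes (so `LHPC` is constrained only to the pooled
deciduous category), chronological age, and enamel microstructure.
Passing recovery tests therefore demonstrates that the *machinery* is
correct and calibrated under the study's declared structure — not that
any particular archaeological inference is right.

## Calibration experiments

`recovery_experiment()` wires the generator to the models:

* **Cell-probability coverage** (`model1_cells`): per replicate, the 18
  true cell logits are drawn from the model's own $N(0,1)$ prior
  (simulation-based calibration — coverage of a correct sampler is then
  nominal by construction), with $\sigma_{\mathrm{ind}} = 0.5$,
  $\sigma_{\mathrm{site}} = 0.3$ and stress curves off so the
  tooth-level generative model coincides with Model 1. Scored: 95% CrI
  coverage of the 18 population-average cell probabilities and the bias
  of the $\sigma_{\mathrm{ind}}$ posterior median. Default problem
  size: 20 replicates of 60 + 60 individuals fitted with 2 chains ×
  (500 + 500) draws.
* **Derivative specificity/sensitivity** (`model2_flat`,
  `model2_increasing`): episode-level rows are simulated directly from
  a constant (0.2) or logistic-ramp curve. For these two experiments
  stage 9 is simulated *like any other stage* rather than as a
  structural zero — with the structural zero a "flat" truth is not flat
  and a false-positive rate would be unmeasurable. Scored: fraction of
  replicates with any flagged segment (flat) and with a flagged
  INCREASE segment (ramp).
* **Peak recovery** (`model2_peaks`): episode rows from the default
  peaked curves at the study's episode-sample size (35 + 37
  individuals), stage 9 structural. Scored: whether the posterior
  median curve's argmax lands within ±1 stage of the generating peak
  (3.5 for UPMH, 6 for NEA).

## Numerical choices and degenerate inputs

* Bernoulli log-likelihood uses log-sigmoid evaluation
  (`plogis(…, log.p = TRUE)` in R, `log1p(exp(…))` branches in C++), so
  it is finite for any finite parameters.
* B-spline bases refuse to extrapolate; evaluation outside the knot
  range is an error everywhere (basis, curves, derivatives).
* Credible intervals are equal-tailed type-7 sample quantiles; the
  odds-ratio reversal identity (OR → 1/OR with mirrored endpoints)
  holds exactly at draw counts where the 2.5/50/97.5 percentiles are
  order statistics, and to interpolation error otherwise.
* Empty inputs are legal where the science allows: a header-only table
  reads as an empty collection, the inclusion filter may return an
  empty dataset, an individual with one tooth has an empty risk set.
  Zero eligible individuals for Model 2, a missing taxon for Model 1,
  and unstageable incisors with furrow defects are hard errors.
* The pipeline writes a manifest (config, seed, package version, step
  log) sufficient to reproduce a run bit-for-bit with the same package
  version; summaries are written with full precision.

## Known limitations

* The stage scale is ordinal-as-continuous in Model 2's smooth; the
  reference age ranges attached to stages are inert annotation, never
  covariates, deliberately sidestepping the debate over Neanderthal
  versus modern dental-development schedules.
* Observability does not require the stage-specific crown third to be
  preserved, only the specimen — episode risk sets are therefore
  slightly optimistic for heavily worn crowns.
* The published per-transition change arrows cannot be reproduced
  without the undeposited raw data; only the flagging mechanism is
  testable, and it is tested on synthetic truth.
* The generator's site-size and teeth-per-individual distributions are
  round-number choices (the real distributions are unpublished) and are
  exposed as configuration for sensitivity analysis.
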