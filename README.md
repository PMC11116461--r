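# lehstress

Bayesian modelling of dental enamel growth disruptions in Paleolithic
hominins.

## What this package is for

Enamel hypoplasia — a localized thinning of tooth enamel — permanently
records physiological stress (illness, malnutrition, weaning) suffered
while a tooth crown was forming. Because crown formation follows a
known schedule, the position of a defect within the crown dates the
disruption in developmental time. `lehstress` provides a tested,
reusable pipeline for comparing the frequency and ontogenetic timing of
such growth disruptions between Neanderthals (NEA) and Upper Paleolithic
modern humans (UPMH), for bioarchaeologists and biological
anthropologists working with tooth-level scoring data.

The pipeline covers:

* **Data handling** — CSV tables of tooth specimens and defect
  observations, validation, and the inclusion filter (crowns with at
  least 50% of height preserved and surfaces in good condition).
* **Staging** — a deterministic 11-stage crown-formation system mapping
  each (tooth class, jaw, crown third) to the developmental stage at
  which that third completes (stage 9 is a formation hiatus), and
  matched **systemic stress episodes**: furrow-form (LEH) defects on
  two or more teeth of one individual assigned to the same stage.
* **Model 1** — a hierarchical Bernoulli GLMM for a tooth carrying at
  least one defect of any form:
  `logit P(defect) = beta[taxon:tooth type] + u[individual] + v[site]`,
  with cell-means coding over the 18 taxon-by-type cells,
  `beta ~ N(0,1)`, `u, v ~ N(0, sigma)`, `sigma ~ Exp(1)`.
* **Model 2** — a hierarchical Bernoulli model for an individual
  experiencing a stress episode at each stage, with a per-taxon
  penalized cubic B-spline smooth over the standardized stage scale
  (shrinkage sd per taxon, `Exp(1)` priors), individual and site
  intercepts.
* **Inference** — a built-in gradient-based no-U-turn sampler (4
  chains, 8000 post-warmup draws by default), convergence gates
  (split R-hat < 1.01, ESS > 10% of draws, MCSE < 5% of posterior sd),
  posterior predictive checks, population-average cell probabilities
  and taxon averages, pairwise odds-ratio contrasts between taxa (per
  tooth type, and at stages 3 and 6 for the episode model), fitted
  stage curves, and change-period detection via central
  finite-difference first derivatives whose 95% credible interval
  excludes zero.
* **Synthetic cohorts** — a seeded generator reproducing the study's
  declared structure (74 + 102 individuals, 56 sites, 423 + 444
  included teeth in expectation, taxon-specific stage-wise stress
  curves) with known ground truth, plus recovery/calibration
  experiments.

## Worked example

Simulate a default synthetic cohort, detect matched stress episodes,
and fit the episode-level model:

```r
library(lehstress)

cohort  <- generate_cohort(synthetic_config(), seed = 1)
dataset <- filter_included(cohort$dataset)
dataset
#> <leh_dataset> 802 specimens (383 NEA, 419 UPMH), 357 defects

episodes <- match_episodes(dataset)
nrow(episodes)
#> [1] 92

design <- build_design_model2(dataset, episodes)
fit    <- run_mcmc(design, seed = 1)
diagnose(fit)
#> <leh_diagnostics> 158 parameters | max R-hat 1.0007 | min ESS 2672 | overall PASS

pairwise_odds_ratios(fit, stages = c(3, 6))
#>    label  or_median or_lower95 or_upper95 excludes_one
#> 1 stage3 0.09485632 0.02401657   0.306127         TRUE
#> 2 stage6 3.93187559 1.56513653  10.394758         TRUE

derivative_segments(fit)
#>   taxon start  end     sign
#> 1   NEA  2.90 5.00 INCREASE
#> 2   NEA  6.50 8.75 DECREASE
#> 3  UPMH  4.65 7.60 DECREASE
```

Reading the output: the odds of a Neanderthal individual experiencing a
systemic stress episode at stage 3 are about a tenth of the UPMH odds
(CrI excludes 1), while at stage 6 they are about four times higher —
the generating curves place the UPMH stress peak early (stage 3.5) and
the Neanderthal peak late (stage 6), and the model recovers that
crossover. The derivative segments flag the stages over which each
fitted curve credibly rises or falls.

The same steps run end-to-end, with artifacts
(`episodes.csv`, `summaries.json`, `curves.tsv`, `diagnostics.json`,
`manifest.json`), via:

```r
run_pipeline(run_config(synthetic = synthetic_config(),
                        out_dir = "leh_run", seed = 1))
```

or from a shell through `inst/scripts/leh-pipeline.R`.

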