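---
title: "Classifying individual deaths as excess or expected during extreme heat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying individual deaths as excess or expected during extreme heat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatexcess)
```

## The problem and the core idea

Extreme hot-weather events raise population mortality, but the excess
deaths are almost never certified as heat-related: in the vital
statistics they look like the expected deaths that would have occurred
under typical weather. The framework in this package rests on four
premises: (1) some event-period deaths are expected regardless of
temperature; (2) those expected deaths resemble typical-summer deaths
with respect to characteristics of the decedents, their neighborhoods,
and the circumstances of death; (3) a case–control model comparing
*only expected* deaths with typical-weather deaths should therefore be
null; (4) if the expected *number* of deaths is repeatedly sampled from
all event-period deaths, the individuals whose presence consistently
makes models non-null are the likelier excess deaths.

Five covariates with established hot-weather mortality associations
drive the models, with expected coefficient directions
(`direction_expectations()`): younger age category (<75 years,
positive), location of death (any category riskier than the hospital
reference), neighborhood deprivation quintile (positive), population
density quintile (positive), and residential greenness NDVI (negative).
Age is dichotomized at 75; deprivation and density quintiles enter as
continuous scores; NDVI is continuous.

## The procedure

With a case pool of size $N$, a control pool, and an externally supplied
expected count $E$:

1. **Repetition.** Draw $E$ cases and $rE$ controls (default ratio
   $r = 4$) without replacement; fit the logistic model(s); convert the
   fits into a non-negative integer weight (below). Record, per case,
   the selection tally $A$ and the weight-sum tally $B$.
2. **Trial.** After `n_reps` repetitions, rank cases by the probability
   ratio $B/A$ (descending) and flag the top $N - E$ as the trial's more
   probable excess deaths.
3. **Combination run.** Over `n_trials` independent trials, compute each
   case's flag percentage, mean rank, and rank standard deviation; label
   the $N - E$ cases with the highest flag percentages
   `probable_excess`, the rest `probable_expected`.

The study-scale defaults mirror the motivating application: $N = 411$,
$E = 297$ (from average typical-summer-week mortality — the package
takes $E$ as an input and deliberately does not estimate baselines),
11,632 controls, 10,000 repetitions, 100 trials. Tests and the
acceptance script run reduced scales (typically 10 trials × 500
repetitions, and pools of a few hundred to a few thousand records for
unit-level checks), chosen so the full suite completes in minutes while
leaving Monte-Carlo error well inside the asserted tolerances.

### The twelve modeling combinations

`standard_combinations()` crosses four choices:

| choice | variants |
|---|---|
| model type | five univariate models vs one multivariate model |
| significance tally | per model (univariate); at least one significant variable, or count of significant variables (multivariate) |
| coefficient direction | required to match expectation, or ignored |
| alpha | 0.10 or 0.05 |

A term is significant when its fit converged, its two-sided Wald p-value
is below alpha, and (if required) its sign matches the expectation. The
location factor counts as **one variable**, significant when any of its
three indicators is (direction applied per indicator); the alternative
of counting indicators separately is a documented open choice we
rejected because the framework consistently treats the analysis as
five variables. Univariate combinations draw a **fresh sample per
variable model** (five independent draw-and-fit steps per repetition,
tallies summed across variables); reusing one sample per repetition
would be equally defensible, but fresh draws keep the five models
independent and leave the expected ratios unchanged.

## Synthetic cohorts with known truth

The original administrative data are not public, so the generator
(`scenario_params()`, `simulate_cohort()`) creates pools with known
ground truth. Expected-type cases are drawn from the *control*
marginals — exactly the exchangeability premise of the framework —
while excess-type cases come from marginals perturbed by a per-variable
shift: additive log-odds (softmax-renormalized) for categorical
variables, an additive mean shift for NDVI. `shift_for_target()` inverts
a target profile into a shift, so the strong-effect preset
(`scenario_strong()`) reproduces the consensus profile of decedents
identified as excess by all twelve combinations: 96.7% under 75, 80%
home / 20% other-location deaths, two-thirds in the most deprived
quintile, 60% in the densest quintile, mean NDVI 0.254 against a control
mean of 0.329. Death dates over the seven event days follow per-type
weight vectors; the strong preset concentrates excess deaths on the
hottest three days (20/23.3/20%), with expected-type dates uniform.

Choices a scientist had to make where no published value exists:

- **NDVI spread.** NDVI is treated as normal (truncated to $[-1, 1]$,
  a formality at these parameters) with SD 0.1, which makes the
  excess/control mean gap about 0.75 SD — detectable but far from
  separable, matching the notion of a neighborhood-level exposure proxy.
- **Deprivation marginals.** The published control percentages sum to
  99.9%; the generator renormalizes proportionally.
- **Ages.** Only the <75 indicator is analyzed; integer ages are filled
  uniformly within the band for realism of the record format.
- **Independence.** The five covariates are generated independently:
  only marginal structure is emulated, because only marginals are
  documented. Real vital-statistics data are correlated (deprivation
  with density, greenness with both), and that correlation plausibly
  matters for which modeling combination is most stable — see
  *What the simulations do and do not show*.

Scenario generation is a deterministic function of the parameter set and
seed; pools, truth labels, and a manifest can be written to CSV/JSON
(`write_scenario()`, or the `simulate` CLI subcommand).

## Numerical choices

- **Fitting.** Maximum-likelihood logit via iteratively reweighted least
  squares (`stats::glm.fit`), intercept always included, at most 100
  iterations, deviance tolerance $10^{-8}$. Inference is a Wald z-test
  per coefficient (estimate / SE against the standard normal), the
  default reported by standard logistic software.
- **Separation and non-convergence.** A repetition whose fit fails to
  converge, or shows a boundary fitted probability (within 10 machine
  epsilons of 0/1) together with an exploding coefficient (>10) or SE
  (>100), contributes weight 0 but still counts toward the selection
  tallies $A$ — discarding it would bias the denominators. Occurrences
  are counted on the result object. Aliased (rank-deficient) columns get
  `NA` estimates and are never significant.
- **Quintile binning.** `quintile_bin()` uses type-7 sample quantiles;
  boundary ties all fall to the lower bin (deterministic and
  order-independent); published cut points can be supplied directly.
  Density quintiles are computed **once over the pooled case+control
  records**: quintile membership is an attribute of a decedent's
  neighborhood, and per-repetition re-binning would make tallies
  incomparable across repetitions.
- **Ties and zero denominators.** Within a trial, equal ratios are
  ordered by a random permutation drawn once per trial from the trial's
  stream (id order would bias flags toward file order). At the
  combination level, equal flag percentages are ordered by **mean rank**
  before any random tie-break: with few trials the flag percentage takes
  only `n_trials + 1` values and the label boundary can fall inside a
  large tie block, so discarding the trials' own rank evidence there
  costs real accuracy; at 100 trials the secondary key rarely binds.
  Cases never sampled in a trial ($A = 0$, realistic only at reduced
  scale) receive ratio 0 with a warning — absence of evidence ranks low
  rather than excluding the case.
- **Rank SD.** The sample ($n-1$) standard deviation across trials;
  undefined (`NA`) for a single trial, in which case labels are still
  produced.
- **Reproducibility.** One master seed per run; each trial runs on an
  independently derived substream, so any trial can be reproduced in
  isolation and trial order is immaterial. A run's manifest (config,
  seed, version) suffices to reproduce every output.

## Assessment suite

`compare_to_controls()` applies the documented battery — Welch t for
NDVI (robust to the 114-vs-11,632 size imbalance; the pooled-variance
choice is not documented anywhere we could follow), chi-square for age
and location (Yates correction on the 2×2 age table only, switchable;
categories empty in both groups are dropped with a note), Wilcoxon
rank-sum with tie correction for the heavily tied ordinal quintiles
(exact enumeration only for tie-free samples with a group ≤ 25).
`overlap_percent()` and `consensus_set()` quantify agreement between
combinations' probable-excess sets; `daily_distribution()` summarizes
labels over event days; `recovery_metrics()` scores labels against
synthetic truth (sensitivity, specificity, PPV). With the enforced
$N - E$ positives, an uninformative classifier has expected sensitivity
$(N-E)/N$ — 114/411 ≈ 0.277 at study scale — which is the correct
chance floor for all recovery comparisons.

## What the simulations do and do not show

The acceptance script (`scripts/acceptance.R`) recomputes, per seed, the
structural counts, recovery sensitivities on the strong and null
scenarios, rank-stability summaries, calibration, and day-concentration
quantities. Three findings from these runs deserve explanation, because
they illuminate the method's operating regime:

- **Calibration is a fresh-data property.** With new data every
  repetition, the univariate Wald rejection rate for single-coefficient
  variables sits at alpha (the location factor, significant when any of
  three indicators is, sits between alpha and the family-wise bound
  $1-(1-\alpha)^3$). *Conditional on one fixed cohort*, repetitions
  reuse ~72% of the case pool, so rejection rates concentrate around the
  pools' realized differences instead — exactly the signal the
  framework exploits to rank cases. Both behaviors are tested.
- **Very strong effects saturate the tallies.** Under the consensus
  profile shift, four of the five variables are significant in
  essentially every repetition; the per-repetition weight then varies
  mostly through the marginally significant greenness term, and the
  any-significant tally rule carries almost no case-level information at
  all (its recovery sits at the chance floor). The count rule retains a
  graded signal and recovers truth well above chance, but the margin is
  smaller than in a moderate-shift regime, where recovery is markedly
  better. The method is most informative when effects keep models near
  the significance threshold, so that individual cases can tip them.
- **Rank-stability orderings are regime-dependent.** On these
  independent-covariate synthetic cohorts the count-weighted
  multivariate ranking is *more* stable across trials than the
  univariate ranking — under saturation the four always-significant
  univariate models dilute the informative model's contribution to the
  summed tallies and amplify relative rank noise. Observed stability
  orderings on real data, where all five variables carry correlated,
  marginal signal, need not transfer to this synthetic regime, and vice
  versa. Passing recovery tests here validates the machinery and its
  bookkeeping, not any claim about which combination is best on real
  administrative data.

## Known limitations

- The generator emulates marginals only; no covariate correlation, no
  temperature–mortality dose-response, no mortality displacement, no
  co-exposures. Conclusions about combination choice on real data should
  not be read off synthetic stability orderings.
- The expected count $E$ is an input; mis-specifying it shifts the
  enforced label split directly.
- At reduced trial/repetition counts the flag-percentage granularity and
  $B/A$ Monte-Carlo noise dominate near the label boundary; the mean-rank
  tie-break mitigates but does not remove this.
- Exact logistic regression, penalization, interactions, and model
  selection are out of scope, as are geocoding and the construction of
  the deprivation, density, and greenness exposures themselves.
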