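---
title: "Models and methods for cross-species event-timing translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for cross-species event-timing translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devtiming)
```

## The problem

Neurodevelopmental milestones — peak neurogenesis of a brain structure, eye
opening, tract formation — occur in a broadly conserved order across mammals,
but on wildly different absolute schedules: an event at post-conceptional (PC)
day 14 in mouse may fall past PC day 100 in macaque. The empirical record is a
sparse species × event table: most timings are documented in a few
well-studied rodents, while primate entries are scarce and concentrated among
early events. `devtiming` fits models to the observed cells of that table and
predicts the unobserved ones, so that a timing measured in one species can be
translated into an expected PC day in another.

Two models are implemented, deliberately matched in complexity:

1. **The offset-log dummy regression** (`fit_fd()`). For species $i$ and
   event $j$,
   $$\ln(\mathrm{PC}_{ij} - k) = \mu + \alpha_i + \beta_j
     + \gamma_1 [\text{primate} \times \text{cortical}]
     + \gamma_2 [\text{primate} \times \text{limbic}] + \varepsilon_{ij},$$
   with binary indicator predictors, one base species and one base event
   dropped to keep the design full rank. The offset $k$ (days) absorbs early
   organizational development — implantation, blastulation, germ-layer
   differentiation — assumed roughly shared across species; it is either fixed
   (the historical value is 7) or estimated from data, constrained to
   $(0, \min \mathrm{PC})$. The two interaction terms allow primate cortical
   and limbic events to deviate from the additive schedule.
2. **A single-hidden-layer feed-forward network** (`fit_ffnn()`). The same
   $s + e$ binary indicators feed $h$ logistic hidden units and a linear
   output, optionally with a direct linear (skip) path:
   $$\hat y = b_0 + \sum_{m=1}^{h} v_m\,
     \sigma\!\big(b_m + w_m^\top x\big) \;\{+\; u^\top x\},
     \qquad \sigma(z) = \frac{1}{1 + e^{-z}}.$$
   The response is $\ln \mathrm{PC}$ (no offset); training minimizes the sum
   of squared errors plus a weight-decay penalty
   $\lambda \sum \theta^2$ over *all* parameters. The network imposes no
   functional form: with the hidden path silenced the skip term is exactly
   ordinary linear regression, and the logistic unit lets it bend away from
   additivity where the data ask for it.

With 10 species and 95 events the regression has $9 + 94 + 2 + 1 = 106$
linear coefficients plus the separately estimated $k$ (107 parameters), and
the one-unit skip-free network has $1 \times 106 + 2 = 108$ — close enough
that differences in predictive behaviour reflect the model class, not raw
capacity.

## Why the natural log, and nothing fancier

Raw PC days are strongly right-skewed: late events in slow-developing species
stretch the tail by an order of magnitude. The log transform is applied purely
to compress that dynamic range — no normality assumption is attached to it,
and no variance-stabilizing family (e.g. Box–Cox) is searched.
`distribution_summary()` reports moment-based (Fisher–Pearson) skewness and
excess kurtosis, the plainest estimators of the quantities of interest, so the
raw-versus-log comparison is easy to reproduce:

```{r skew}
tab <- generate_events(synthetic_spec(seed = 11))$table
rbind(raw = distribution_summary(tab$pc_day),
      log = distribution_summary(log_transform(tab$pc_day)))
```

## Estimating the offset

`estimate_k()` profiles a uniform grid of 200 candidate offsets over
$[\delta, \min \mathrm{PC} - \delta]$ with a guard band $\delta = 0.01$ day,
refitting the regression at each and scoring the Pearson correlation between
observed days and back-transformed fitted days, $\exp(\hat y) + k$. A grid —
rather than a golden-section search — is used because the profile is not
guaranteed unimodal; ties break toward the smaller offset. The correlation is
computed on the original day scale by default because the quantity being
translated is a day; the log-scale alternative is exposed via `scale = "log"`.

The grid winner is then sharpened by a bounded Brent search inside its
bracketing interval (`refine = TRUE`). This matters only in the near-noiseless
regime: a generative offset almost never sits exactly on a 200-point grid, and
the ~0.01–0.1 day discretization error it leaves behind dominates every other
error source there. Refinement is cheap (one extra fit per Brent evaluation)
and changes nothing detectable on noisy data.

Only the single QR factorization of the design is reused across the grid —
the response, not the design, depends on $k$ — which is what makes
re-estimating $k$ inside every cross-validation fold affordable. Re-estimating
per fold is not optional: freezing a globally estimated $k$ would leak the
held-out observation into its own prediction.

## Training the network

The penalized loss is minimized by full-batch BFGS with the analytic gradient
(verified against central finite differences in the test suite); the data sets
involved are a few hundred rows, so stochastic optimizers would add variance
for no benefit. Weights initialize uniformly on $[-0.5, 0.5]$ from an explicit
seed, and every fit is bitwise-reproducible given (data, architecture, seed).
Because the loss surface is multimodal, table-level fits and all
cross-validation runs train from multiple random restarts (10 by default) and
keep per-restart results.

Two conventions worth noting:

* **Biases are included in the decay penalty.** Keeping the penalty a single
  scalar contract over the whole parameter vector is simpler to state and
  test, and matches the reference behaviour of classical neural-regression
  implementations.
* **All $s + e$ indicators are kept** (no base dropping, no intercept column).
  The network has its own biases, and the decay penalty handles the resulting
  redundancy; dropping levels would only complicate query encoding.

Non-convergence within `max_iter` is recorded on the fit object rather than
raised: the best-so-far parameters are still a valid (if suboptimal) restart,
and the restart mechanism is the intended remedy.

## Leave-one-out selection and evaluation

Known observations number a few hundred, so leave-one-out is used instead of
$k$-fold: each observation is predicted from a model trained on the others.
The coverage filter (`filter_min_coverage()`, iterated to a fixed point since
dropping events can strand species and vice versa) guarantees the held-out
cell's species and event stay represented in every training fold.

The selection criterion is the mean squared error **in days** — predictions
are back-transformed before scoring — computed per restart and averaged
across restarts (the alternative, scoring restart-averaged predictions, is
available via `average = "predictions"`). `grid_search()` scans hidden-unit
counts and a decay grid (default: 0 plus 21 points log-spaced on
$[10^{-3}, 1]$, which brackets the region where the error typically turns
upward) and returns the argmin, ties broken toward the smaller network, then
the smaller decay. Restart seeds derive deterministically from the master
seed and the held-out cell's identifiers, not its row position, so results
are invariant to input row order; fitters also sort observations canonically
before factorizing, which makes that invariance exact in floating point
rather than approximate.

Error anatomy uses the absolute day-scale error per observation and the
exceedance count $N(\theta)$ — how many observations miss by more than
$\theta$ days — decomposed into primate and non-primate contributions
(`error_profile()`), with strict inequality at the threshold. Profiles from
two models on the same observations can be intersected
(`profile_overlap()`) to find events that *both* models predict badly; such
events are more plausibly hard (tail timings, thin species coverage) than
artifacts of either model class.

## The synthetic generator

`synthetic_spec()`/`generate_events()` produce tables with the structure the
models assume, plus the known truth, so every stage is testable without any
external download and parameter recovery can be measured exactly:

$$\mathrm{PC}_{ij} = k_{\mathrm{true}} + \exp(\alpha_i + \beta_j +
\varepsilon_{ij}), \qquad \varepsilon_{ij} \sim N(0, \sigma^2).$$

Choices and defaults, fixed once:

* **Shape matches the empirical record**: 10 species (2 primates), 95 events,
  60% of cells unobserved, matching the 372-of-950 observed density of the
  empirical table the models were developed for.
* $\sigma = 0.1$ on the log scale, i.e. ~10% timing noise — the order of
  inter-laboratory disagreement in published event timings.
* $k_{\mathrm{true}} = 5$ days; species effects $N(0, 0.7)$, event effects
  $N(2.5, 0.9)$ sorted ascending so high indices are late events. The
  resulting PC days run from under a week to a few hundred days, the span of
  small-rodent-to-primate development.
* **Primates are the slowest developers**: the `n_primates` species with the
  largest effects are flagged primate. Their cells, and cells of the latest
  third of events, are masked with multiplicatively higher probability
  (defaults 1.6 and 1.5), emulating the literature's thin primate and
  late-event coverage; the per-cell rates are normalized so the overall
  missing fraction stays on target, then minimally repaired (re-adding the
  cells that relieve the tightest deficits, deterministically) until the
  coverage constraints hold.
* **Event classes** are a shuffled balanced cortical/limbic/other assignment,
  so the interaction columns stay identifiable even in small test tables.
* `primate_noise_multiplier` (default 1) optionally inflates primate noise,
  for experiments probing why primate events resist prediction.
* A generative interaction is deliberately absent: the additive-log form is
  the regression's own model, so regression recovery is exact in the
  noiseless limit and any network advantage must come from real
  nonlinearity in the data, not from a rigged generator.

What the generator does **not** emulate: phylogenetic covariance between
species (each species effect is independent), event-specific noise,
measurement round-off, or any resemblance to the actual published timing
values. Passing recovery tests on these tables therefore demonstrates
correctness of the machinery, not real-data accuracy.

## Numerical conventions and degenerate inputs

* Least squares is solved by QR, never by inverting normal equations; rank
  deficiency is reported with the names of the offending columns (the most
  common cause: no primate observations of a class, zeroing an interaction
  column).
* Offsets must satisfy $0 \le k < \min \mathrm{PC}$; violations are domain
  errors, as are nonpositive days anywhere.
* Zero-variance observed values make the correlation criterion undefined and
  raise an error rather than returning an arbitrary offset.
* Queries for species or events absent from training have no coefficient and
  raise an "untrainable query" error instead of extrapolating.
* Regression predictions are $\exp(x^\top\hat\beta) + k > k$; network
  predictions are $\exp(\hat y) > 0$. Neither can produce a negative day.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated tables,
sized so the full suite completes in minutes while still exercising
full-scale structure: parameter-count and filtering checks on a 10 × 95–106
grid; regression leave-one-out at full scale (~400 observations); network
leave-one-out and the decay grid at reduced scale (6–8 species, 15–30 events,
2–3 restarts), where behaviour is representative but each cell costs tens of
network fits rather than thousands. The offset-recovery experiments use
10 × 30 grids at 50% missingness with 20 replicate seeds.

## Limitations

* Predictions are only defined for species and events seen in training; the
  package completes a partially observed table, it does not extrapolate to
  new species.
* No uncertainty quantification is attached to the regression coefficients or
  the offset; the network's restart spread is reported as a dispersion
  indicator, not a confidence interval.
* Phylogeny is ignored: species are exchangeable dummy levels. Closely
  related species share no strength beyond what the event structure induces.
* The decay grid search treats restart averaging as the estimator of each
  cell's error; with very few restarts the selected $(h, \lambda)$ can be
  noisy, which is why the defaults use ten.
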