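---
title: "A two-stage maximum-likelihood methylation age clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage maximum-likelihood methylation age clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(betaclock)
```

## The model

DNA methylation at age-associated CpG sites drifts over the lifespan, and
microarray platforms summarize each site as a beta value $x \in [0,1]$.
`betaclock` predicts chronological age from a small panel of such sites with
a grid maximum-likelihood estimator rather than a penalized linear
regression. The training phase builds, for each selected site $j$, a
*reference curve* $\mu_j(a)$ of expected methylation at every integer age
$a \in \{0, \dots, 100\}$ and a matching spread $\sigma_j(a)$. Prediction
then scores an observed profile $x$ against every candidate age,

$$
L(a) \;=\; \sum_{j \in \text{available sites}} \log f\!\left(x_j \mid \mu_j(a), \sigma_j(a)\right),
$$

and reports $\hat a = \arg\max_a L(a)$. Because the sum simply skips sites
that are missing in a sample (intersection semantics), the clock degrades
gracefully with missing probes instead of requiring imputation.

Two density families $f$ are available. The default is a normal density
with mean $\mu_j(a)$ and standard deviation $\sigma_j(a)$. The alternative
is a Beta density whose shape parameters come from the method-of-moments
inversion

$$
\alpha = \frac{\mu(-\mu^2 + \mu - \sigma^2)}{\sigma^2}, \qquad
\beta = \frac{(\mu - 1)(\mu^2 - \mu + \sigma^2)}{\sigma^2},
$$

valid when $0 < \sigma^2 < \mu(1-\mu)$. In practice the two families
produce nearly identical predictions (the test suite asserts a median
disagreement of at most one year on a noisy synthetic cohort), which is why
the simpler normal family is the default.

### Training

1. **Site ranking.** The Spearman rank correlation $\rho_j$ between
   methylation and age is computed per site (pairwise-complete, midranks for
   ties). Spearman is used because the methylation-age relationship is
   monotone but saturating — faster change in childhood, slower later — so a
   rank correlation is the robust choice. Sites with $|\rho_j| < 0.60$ are
   screened out once on the full training population; the top 16 sites by
   $|\rho|$ (ties broken by probe id) form the panel.
2. **Trend curves.** For each panel site, a LOWESS smoother (tricube
   local-linear regression, smoothing fraction $\tau = 0.7$) is fitted to
   methylation versus age. Grid values come from linear interpolation
   between the fitted values at observed ages and are clipped to $[0,1]$;
   outside the observed age range the curve is held constant rather than
   extrapolated.
3. **Variance curves.** Samples sharing an integer age are treated as
   technical replicates: age bins with at least 3 values contribute a
   (mean methylation, unbiased variance) support point, and a second LOWESS
   fit of variance against bin mean gives a smooth lookup from methylation
   *level* to variance. $\sigma_j(a)$ is the square root of this lookup
   evaluated at $\mu_j(a)$, floored at `sigma_floor` (default 0.01 in
   beta-value units) so that a nearly empty bin can never produce a
   degenerate spike likelihood.

### The second stage

Methylation changes rapidly during development and more slowly in
adulthood, so a single panel and curve set fitted to all ages compromises
on both regimes. The two-stage design addresses this: after a first-stage
model is trained on everyone, the training data are split at a cutoff age
into a *junior* cohort (real age $\le$ cutoff) and a *senior* cohort, and
the entire selection + curve-fitting pipeline is rerun inside each cohort
(re-ranking within the screened site universe). At prediction time every
sample first receives a stage-1 estimate; samples with stage-1 age at or
below the routing threshold are re-predicted by the junior model, the rest
by the senior model. The routing threshold equals the training cutoff — at
the published optimum of 25 this is the familiar "25 or younger / 26 or
older" routing.

The cutoff itself is chosen by scanning candidates 10-30: for each
candidate the cohort models are retrained and a held-out validation set is
scored, and the candidate with the smallest *absolute* mean bias error is
selected (ties toward the smallest candidate). Bias rather than absolute
error drives the choice because low bias is this framework's defining
advantage over regression clocks. "Smallest |MBE|" is our reading of
"lowest MBE": a large negative bias is not better than a small positive
one, and on data where the scan's MBE stays positive the two readings
coincide.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tau` | 0.7 | fraction | LOWESS window: fraction of points per local fit (both trend and variance curves — the original optimization reports a single scanned value, so we apply it to both) |
| `n_sites` | 16 | count | panel size per reference matrix |
| `min_abs_rho` | 0.60 | – | Spearman screen threshold |
| `family` | normal | – | likelihood family (`beta` optional) |
| `sigma_floor` | 0.01 | beta SD | lower bound on reference spread |
| `min_bin_size` | 3 | count | smallest age bin contributing a variance point (3 is the smallest count with a meaningful unbiased variance) |
| `min_cohort_size` | 30 | count | smallest cohort the two-stage split accepts; LOWESS at $\tau = 0.7$ needs a minimally populated age range |
| `x_eps` | 1e-6 | – | boundary clipping for the beta family (array beta values can reach 0/1 exactly) |
| `feasibility_fraction` | 0.99 | – | cap on $\sigma^2 / (\mu(1-\mu))$ before shape inversion |

Numerical tie-breaks are deterministic throughout: equal $|\rho|$ resolves
by probe id, equal likelihood resolves toward the youngest age, equal
|MBE| in the cutoff scan resolves toward the smallest cutoff.

## The synthetic-data generator

Real array compilations of the necessary size are multi-gigabyte downloads,
so the package ships a generator (`simulate_dataset()`) that reproduces the
statistical structure the clock assumes and nothing more:

* informative sites follow monotone trends
  $\mu_j(a) = b_j + s_j\, g(a)$ with $g$ logarithmic
  ($\log(1+a)/\log(1+a_{\max})$, the default, reflecting saturating
  trajectories), linear, or piecewise-linear with a steeper slope below a
  changepoint (slope ratio 4, changepoint 20 by default) — the two-regime
  caricature that motivates the second stage;
* amplitudes $|s_j|$ are drawn from $[0.25, 0.6]$ with random sign, the
  dynamic range typical of strongly age-correlated array CpGs, and
  baselines keep every curve inside $[0.05, 0.95]$;
* noise is Gaussian on the beta scale, clipped to $[0,1]$, with
  level-dependent variance
  $v(\mu) = \text{noise\_scale}^2 (1 + 4\mu(1-\mu))$ by default (largest at
  intermediate methylation, as observed on arrays); a moment-matched Beta
  noise family is available since the clock itself models both;
* optional constant sex offsets on a quarter of the informative sites, and
  uniform missingness.

The default `noise_scale` of 0.03 is a stand-in for array-scale technical
noise, not a calibration to any particular corpus. Ages are drawn as
integers because the reference grid is in whole years. What the generator
deliberately omits: probe-level intensity channels, batch effects,
cell-composition heterogeneity, and realistic correlation *between* sites.
Tests passing on these cohorts therefore demonstrate the estimator's
correctness and its qualitative behavior, not clinical-grade accuracy on
real blood methylomes.

## Numerical choices and degenerate inputs

* **LOWESS semantics.** Windows contain $\lceil \tau n \rceil$ nearest
  points; weights are tricube $(1-(d/h)^3)^3$ with $h$ the window radius.
  A degenerate windowed design (all abscissae equal) falls back to the
  weighted mean. Fewer than 3 points, or all-identical ages, are hard
  errors. Robustifying iterations exist but default to 0 (plain weights).
* **Infeasible Beta moments.** Near $\mu \to 0/1$ the floored variance can
  exceed $\mu(1-\mu)$; the variance is clipped to 99% of the bound before
  inversion rather than erroring, since this is a boundary artifact, not a
  data problem.
* **Serialization.** Models are versioned JSON with all grids stored at 17
  significant digits, which makes save/load bit-exact and keeps prediction
  independent of the smoothing implementation; a schema-version mismatch is
  a hard error.
* **Variance support edge cases.** Two usable bins interpolate linearly;
  one bin (or fewer) degrades to a pooled variance with a warning.

## Known limitations

**Smoothing bias on strongly curved trends.** A local-linear smoother with
$\tau = 0.7$ averages over a window spanning most of a century of ages. On
the strongly saturating $\log(1+a)$ trajectories the generator produces by
default, the fitted curve is displaced by up to a few hundredths of a beta
unit near the young-age boundary — worth several *years* of age shift where
the trend is already flattening. This bias is a property of the method
(any implementation of LOWESS at this fraction shows it), is independent of
the trend amplitude, and is the main reason single-stage predictions on
saturating synthetic cohorts carry a positive mean bias of one to two
years. The second stage exists precisely because the single set of curves
cannot serve both age regimes; on piecewise cohorts the junior-cohort MAE
roughly halves after routing.

**Plateau ties at cohort boundaries.** Cohort references are
constant-clamped outside their cohort's observed age range. A sample routed
to the senior model whose beta values sit below that plateau ties exactly
across all plateau ages, and the deterministic youngest-age tie-break then
returns the grid minimum. The same behavior follows from a first-index
argmax in any implementation. Practically this produces occasional gross
under-predictions for samples misrouted across the boundary, and it pushes
the minimal-|MBE| cutoff in our piecewise simulations below the generative
changepoint. Re-breaking ties toward the routed cohort would hide, not
remove, the underlying misrouting.

**Chronological, not biological, age.** The clock targets chronological
age from a 16-site panel; it makes no claim about biological aging rates,
and its accuracy ceiling is set by panel size by design.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 300-2,700
samples over 16-100 sites — large enough for stable Spearman ranks,
age-bin variance estimates, and out-of-sample error surfaces, while a full
run stays in the minutes range on a single core. All simulations are
seeded; identical configurations reproduce bit-identical datasets.

## A minimal session

```{r example}
sim <- simulate_dataset(sim_config(
  n_samples = 800, n_sites = 40, n_informative = 16,
  curve_family = "piecewise", changepoint_age = 25, seed = 7))
train <- subset(sim$dataset, samples = 1:600)
test  <- subset(sim$dataset, samples = 601:800)

model <- train_two_stage(train, cutoff = 25)
model

pred <- predict_two_stage(model, test)
head(pred, 3)

unlist(compute_metrics(pred$final_age, test$ages))
```
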