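---
title: "Estimating host-plant carrying capacity for Viola-feeding fritillaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating host-plant carrying capacity for Viola-feeding fritillaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(violacap)
```

## The question and the model

Whether a declining herbivore population is limited by its larval food plant
comes down to a comparison: how many individuals could the standing host
biomass feed, versus how many are actually there? `violacap` answers the
first half for *Viola*-feeding *Speyeria* butterflies with two identities,

$$\text{Leaf Area Present} = S \times D \times L \times A, \qquad
\#\text{Pupae} = \frac{\text{Leaf Area Present}}{C},$$

where $S$ is the reference ground area (m²), $D$ the plant density
(plants/m²), $L$ leaves per plant, $A$ area per leaf, and $C$ the total leaf
area one larva consumes from first instar to pupation. Every term except $S$
is a random quantity estimated from field or lab data, so the pupae count is
a distribution, not a number. The key assumptions inherited from this
formulation: larvae find and fully consume every plant (so the result is an
upper bound on what the biomass *present* can support), consumption measured
on a surrogate host in the lab transfers to the field, and plant traits are
independent of one another.

## Input distributions

**Plant density.** Belt-transect surveys of a patchily distributed plant
yield per-segment densities with a large spike of exact zeros (empty
segments) and a right-skewed positive part. We model this as a mixture of a
point mass at zero (weight $w$) and an exponential density (rate $\lambda$)
on the positives. With zeros detected by exact equality — densities are
count/area, so zeros are exact by construction — the MLE is closed form:
$\hat w = n_0/n$ and $\hat\lambda = 1/\bar{x}_{+}$, the reciprocal mean of
the positive values. The mixture mean is $(1-\hat w)/\hat\lambda$.
`fit_ziexp()` implements this; `likelihood_ratio_test()` compares it against
a single exponential fitted to all values (see *Limitations* for an
important caveat about that comparison).

**Leaves per plant, leaf area, consumption.** `fit_family()` fits each of
normal, log-normal, left-truncated normal, gamma and Weibull by maximum
likelihood and `select_best_model()` keeps the lowest AIC
($2k - 2\ell$; $k = 2$ for all of these, 1 for the exponential). Closed-form
estimators are used where they exist (normal, log-normal, exponential), with
the variance-type estimates on the $n$ denominator — the MLE, not the
unbiased estimator — so log-likelihoods and AICs are comparable across
families. Gamma, Weibull and the truncated normal are maximised numerically.

**Truncated normal.** Standard fitting functions do not cover a normal
truncated to $[0, \infty)$, so the log-likelihood
$$\ell(\mu, \sigma) = \sum_i \left[\log \varphi\!\left(\tfrac{x_i - \mu}{\sigma}\right) - \log \sigma - \log\!\left(1 - \Phi\!\left(-\tfrac{\mu}{\sigma}\right)\right)\right]$$
is implemented directly (`truncated_normal_loglik()`). The truncation point
is fixed at 0 rather than estimated: all four data types are non-negative
measurements, and a free lower bound would add a parameter the data cannot
inform below their minimum. The normalising term is computed with
`pnorm(..., log.p = TRUE)` so the likelihood stays finite when $\mu/\sigma$
is far negative.

## The Monte Carlo simulation

`run_simulation()` performs, per iteration: one draw each of $L$, $A$, $C$
from their fitted families, and $D$ as the **mean of 1,000 mixture draws**.
Averaging a block of density draws keeps an iteration from landing on an
all-zero density while preserving between-iteration variation in mean
density; it also means the density term contributes little variance relative
to the long-tailed $L$ and the divisor $C$, which is what produces the
strongly right-skewed pupae distribution (mean well above median). Drawing
$L$, $A$, $C$ once per iteration — rather than re-drawing per plant or per
leaf — treats an iteration as one realisation of site-level average
conditions; per-plant resampling would average the trait variation away and
collapse the spread of the resulting distribution.

Numerical contracts:

* **Units.** Leaf areas enter in mm² and consumption in cm² at the I/O
  boundary (matching how such data are recorded); both are converted to m²
  internally. A consumption model stated directly in m² (e.g. a Weibull
  scale of 0.027 m² ≈ 270 cm²) is declared with
  `consumption_unit_in = "m2"`.
* **Sampling by inversion.** All draws are quantile transforms of uniforms.
  This makes runs bit-reproducible given `seed`, makes doubling the
  reference area exactly double every iteration's pupae value, and makes a
  stochastically larger consumption model lower every iteration's pupae
  under a shared seed — all of which are tested invariants.
* **Degenerate draws.** A consumption draw of exactly 0 (possible only for
  families whose support touches 0, e.g. a normal) is rejected and redrawn,
  and the redraw count is reported.
* **Quantiles** use type-7 interpolation (R's default) throughout.

`run_sweep()` repeats the simulation over a fixed density grid (default
0.010–0.100 plants/m² in 0.001 steps) with the density-draw stage bypassed,
then `fit_density_regression()` regresses the per-density **medians** on
density by OLS. Medians, not means, are the regression response: the
per-density distributions are right-skewed, the median is the summary whose
linear scaling is of interest, and quartile bands around it depict the
variance widening with density.

## Segment-level capacity

The site-level simulation assumes unlimited larval movement. The opposite
extreme treats each full-length transect segment as an island:
`plants_per_pupa_threshold()` computes how many plants feed one larva at
average leaf metrics (ceiling of $C / (\bar L \bar A)$),
`count_supporting_segments()` counts full-length segments meeting that
threshold, and `extrapolate_pupae()` scales the count by total/sampled area,
taking the floor. Only full-length (30 m) segments are considered by default
so the sampled area is a whole number of equal belts; the threshold is an
explicit argument because it is sensitive to which consumption summary (male,
female, pooled) it is derived from — male-mean consumption at average leaf
metrics gives 10 plants, the pooled mean gives 13. `food_per_area()` and
`area_required_per_larva()` give the uniform-density food view: cm² of leaf
per m² of ground, and the ground area one larva would need to graze.

## The synthetic-data generator

`generate_field_dataset()` emulates the survey's data structure so the whole
pipeline is testable without the original tables: 135 transects with mean
length 92.16 m (gamma-distributed lengths, shape 2 — long and short
transects both occur when lines run from a boundary to a ridge crest — split
into 30 m segments plus any remainder of at least 1 m), a latent per-segment
density from the zero-inflated exponential, and an observed violet count
drawn Poisson(density × area). Sample sizes default to 241 plants for leaf
counts, 349 leaves for areas, and 10 larvae sexed 1:1. The structural zero
weight defaults to 0.55 with the exponential rate set so the mixture mean is
0.037 plants/m²; the weight is a calibration choice (surveys of this plant
find well over half of segments empty) recorded in the dataset manifest, and
the capacity results are insensitive to how the mixture mean is split
between $w$ and $\lambda$ because the simulation consumes only the mean of
1,000 mixture draws.

Two deliberate distortions to keep in mind. Counts are Poisson given the
latent density, so refitting the mixture to count/area data recovers a
*larger* zero weight than the generator's (sampling zeros add to structural
zeros) while the mixture mean is preserved — recovery tests therefore pin
the mean, not $w$ itself. Leaf counts are ceilings of log-normal draws, so
the refitted log-normal absorbs a small discretisation bias. The generator
also makes no attempt at spatial structure: real violets clump between and
within transects, and passing tests on synthetic data say nothing about
spatial availability, only about the distributional pipeline.

`end_to_end_recovery_check()` chains generator → fits → AIC selection →
simulation and compares the simulated mean against the semi-analytic
expectation $S \cdot \bar D \cdot E[L] \cdot E[A] \cdot E[1/C]$ with each
expectation computed by quadrature on the quantile scale.

## Numerical choices

* Numerical fits start from method-of-moments values and run BFGS on
  log-transformed positive parameters (relative tolerance $10^{-10}$,
  500 iterations); non-finite objective values met during line search are
  penalised rather than raised.
* AIC ties within $10^{-9}$ go to the family listed first, so selection is
  deterministic.
* The LRT statistic is clipped below at 0 and referred to $\chi^2_1$; the
  zero weight sits on the parameter boundary under the null, a caveat
  documented here but deliberately not corrected.
* Empty inputs, all-zero density vectors, non-positive data under
  positive-support families, and mismatched sample sizes in the LRT raise
  immediate errors rather than propagating NaN.

## Problem sizes

The shipped tests run the headline simulation at 10,000 iterations × 1,000
density draws (a couple of seconds), parameter-recovery checks at
$n = 10{,}000$ against 3 standard-error bands from the observed information,
the sweep at 2,000 iterations per density over the 91-point grid, and
law-of-large-numbers checks at $10^5$–$10^6$ draws. These sizes keep the full
suite under a minute while leaving Monte Carlo error well inside the asserted
tolerances.

## Limitations

* **The mixture-vs-exponential LRT is scale-dependent.** The mixture
  evaluates exact zeros as a probability ($\log w$) while the exponential
  evaluates them as a density ($\log \lambda$, finite at 0), so the
  comparison mixes discrete and continuous likelihood contributions and its
  sign depends on the measurement scale: on a per-m² density scale the
  fitted exponential rate is large and each zero *rewards* the exponential,
  collapsing the clipped statistic to 0, whereas when the positive values
  sit well away from zero the mixture wins decisively. Treat the test as
  descriptive; the mixture is retained as the density model on structural
  grounds (zeros are real empty segments, not small densities) regardless of
  the statistic.
* The capacity estimate is an upper bound under full availability; host
  finding, larval movement, competition, induced plant defenses, predation
  and parasitism all push the supportable number down. The segment-level
  count brackets the movement assumption from the other side.
* Consumption is measured in the lab on a surrogate host *ad libitum*;
  field consumption on the native host may differ in either direction.
* Trait independence is assumed; if dense patches also carry larger plants,
  the simulation understates the upper tail.
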