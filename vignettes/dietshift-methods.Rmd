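---
title: "Models and methods behind dietshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dietshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dietshift simulates what happens to a population's nutrient adequacy and
diet-related environmental footprint when meat and/or dairy products in a
two-recall (24-hour) food-consumption survey are replaced by plant-based
alternatives. This vignette explains the models the package implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical choices made along the way.

## The replacement engine

A *scenario* names a set of consumed food subgroups (e.g. the five meat
subgroups), a fraction of each targeted consumption record to replace
(1 except for the half-meat scenario, 0.5), and a strategy:

* **quantity** — the replacement food enters with exactly the grams
  removed;
* **energy** — the replacement grams are scaled so the replacement
  supplies the same kilocalories the removed grams did
  (`replacement_g = replaced_g × ED_orig / ED_repl`).

Each targeted consumption record draws its replacement food uniformly
(with replacement) from the candidate list mapped to the record's
subgroup, from a stream seeded per (scenario, strategy). Design choices
worth stating explicitly, because the underlying convention is genuinely
open:

* *Half-meat halves every targeted record* rather than replacing half of
  the records. The per-record split is deterministic in the fraction and
  independent of how finely the survey happens to code eating occasions.
* *The uniform draw is per consumption record* (each occurrence
  re-drawn), not per food code or per person. This is the most literal
  reading of "equal probability per replacement" and maximises averaging
  over candidates, which is why mean outcomes are so stable across
  allocation replicates (`replicate_allocation_cv()` measures this; on
  the default synthetic survey the CV of mean total protein over ten
  replicates is far below 0.01).
* *Combined half-meat × energy*: the replaced half is energy-matched, the
  retained half untouched.
* *Energy-mode guard*: candidates with energy density below 0.05 kcal/g
  are excluded in energy mode. An energy match against a near-zero-energy
  candidate would demand physically meaningless gram amounts; exclusions
  are counted in the scenario log. The floor is far below any realistic
  solid-food or drink density, so on sensible data it never bites.
* *Seed policy*: one master seed; per-(scenario, strategy) allocation and
  bootstrap seeds are derived by a stable string hash, so scenarios are
  reproducible individually and independent of each other.

## The habitual-intake model

Two recall days per person are not a habit: day-to-day (within-person)
variation inflates the spread of observed daily intakes, so comparing raw
daily means against a cutoff such as the EAR overstates the tails. The
package removes the within-person variance with a one-part
measurement-error model for components consumed daily:

$$ g(Y_{ij}) = \beta_0 + \beta_1\,\mathrm{age}_i + b_i + e_{ij}, \qquad
   b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_w^2), $$

where $g$ is a Box–Cox transform with power $\lambda$ chosen on the grid
$\{0, 0.05, \dots, 1\}$ ($\lambda = 0$ is the log), fitted separately per
nutrient and sex, with survey weights entering both the fit and every
population summary.

Numerical choices:

* The transform is normalised by the weighted geometric mean $\bar g$ of
  the intakes, $t = ((y^\lambda - 1)/\lambda)/\bar g^{\,\lambda}$. This
  keeps $\sigma_b, \sigma_w$ on a comparable, log-like scale across the
  whole grid (adjacent grid points otherwise rescale the variance
  components by $\bar g^{\,0.05}$, which for energy is ~1.45) and reduces
  the profile log-likelihood to the classic
  $-\tfrac{W}{2}\log\hat\sigma^2(\lambda)$ form with the Jacobian
  absorbed.
* The age trend is linear on the transformed scale; the variance
  components come from weighted moments ($\sigma_w^2$ from half the
  squared within-person day differences of residuals; $\sigma_b^2$ from
  the person-mean residual variance minus its within-person share,
  truncated at zero with a warning).
* Zero intakes are handled by shifting all values up by half the smallest
  positive intake (recorded on the model and subtracted after
  back-transformation).
* Persons with fewer than two recall days are dropped with a logged
  count: within-person variance is unidentifiable from one day.

This is a deliberately compact implementation of the general
usual-intake methodology (transform, separate the variance components,
reconstruct the population distribution): fractional-polynomial age
trends and spline back-transforms found in full-featured tools are
replaced by a linear age trend and the fixed Box–Cox grid. The age-trend
family is the natural place to extend.

### Reconstructing the habitual distribution

For person $i$ with person-mean residual $\bar r_i$ over $d_i$ days, the
transformed habitual level is estimated by shrinkage towards the age
trend,

$$ h_i = \hat\beta_0 + \hat\beta_1\,\mathrm{age}_i + k_i \bar r_i,
   \qquad k_i = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2 / d_i}. $$

Shrinkage removes estimation noise but also variance: the $h_i$ spread
only $k\,\sigma_b^2$, not $\sigma_b^2$. The package therefore re-expands
each $h_i$ with the variance the shrinkage removed,
$s_i^2 = \sigma_b^2 (1 - k_i)$, integrating the inverse transform over
$N(h_i, s_i^2)$ with fixed 30-node Gauss–Hermite quadrature. The
resulting weighted node values have transformed-scale marginal
distribution exactly $N(\hat\beta_0 + \hat\beta_1\,\mathrm{age},
\sigma_b^2)$, which gives two properties at once:

* the weighted population mean on the original scale is unbiased (for
  $\lambda = 0$ it equals $\exp(\mu + \sigma_b^2/2)$ under the model, and
  for $\lambda = 1$ the back-transform is linear so the mean is preserved
  exactly);
* tail proportions are not shrunken, so the EAR cut-point method reads
  the correct fraction below the cutoff. Using the per-person conditional
  means alone would understate a 5% tail by several percentage points at
  realistic $\sigma_b, \sigma_w$.

"Habitual intake" here means the back-transformed latent level
$g^{-1}(h)$ — for $\lambda = 0$ the long-run *median* daily intake — not
the long-run arithmetic mean of daily intakes (which would carry an extra
$\sigma_w^2/2$ term). All summaries, EAR comparisons and the synthetic
generator's ground truth use this one convention consistently.
Back-transform bases that would be negative (possible for $\lambda > 0$
deep in the lower tail) are clamped at zero and counted.

### Uncertainty and comparisons

95% confidence intervals come from a person-level bootstrap (default
B = 200), stratified by sex because every estimand is sex-specific; both
recall days of a resampled person travel together, and the model is refit
on every resample. A resample on which the fit fails is redrawn, at most
5% of B times. Scenario-versus-reference differences are flagged when the
two bootstrap intervals do not overlap — a conservative convention
matched to how such scenario studies are reported. Survey weights enter
the model fit as observation weights *and* all population aggregation;
weighting only one of the two levels would make the fitted trend and the
population it is applied to inconsistent.

## Environmental footprints

Three per-kg life-cycle factors ride on the food table: greenhouse-gas
emissions (kg CO2-eq), land use (m²·year) and freshwater consumption
(litres). Footprints are linear in consumed grams, averaged per person
across recall days first, then survey-weighted across persons (the same
convention as the intake summaries; with equal day counts the order does
not matter). Relative differences are reported against the reference
diet, and group contribution shares per indicator sum to one. LCA factors
are treated as point values — no uncertainty propagation — which mirrors
how such factors are published.

## The synthetic survey generator

The restricted survey, composition and LCA datasets the method is
normally applied to cannot be shipped, so the package generates a survey
with known ground truth. The generator's defaults are the study
conditions the test-suite validates under: 600 women and 585 men, ages
uniform on 18–65, two recall days, survey weights lognormal with mean 1
per sex; five consumed meat subgroups and seven dairy subgroups plus
plant staples and a fish/egg group; one plant-based replacement group per
targeted subgroup with list sizes averaging 12 (support 1–31); 80% of
meat foods flagged red meat; per-food densities scattered around group
means with relative SD 0.2; $\lambda = 0$, $\sigma_b = 0.30$,
$\sigma_w = 0.50$, a mild negative age trend (−0.003/year on the log
scale), and mean habitual energy of 2000 kcal (women) / 2600 kcal (men).
Replacement foods carry the systematic contrasts of real plant-based
alternatives: all-plant protein, zero B12 (a fortification switch
exists), more fiber, less saturated fat, lower GHG and land factors,
higher water factors — the last because the common alternatives (nut- and
oat-based products, plant drinks) are irrigation-intensive crops.

The intake model is generative in exactly the form the habitual-intake
module assumes. Each person carries a latent transformed level
$H_i = \mu_{\mathrm{sex}} + \mathrm{slope}(\mathrm{age}_i - 40) + b_i$;
each day realises total energy $g^{-1}(H_i + e_{ij})$. A basket of eating
occasions (Poisson occasion counts per group with at least one per staple
group, uniform food choice within group, lognormal portions) is drawn
*once per person* and consumed on both days, with all gram amounts
rescaled so the day's energy hits its target exactly. Two further
normalisations keep the generator exactly on-model:

* group-level energy shares are pinned at their expected values, so diet
  *composition* does not vary between persons beyond food choice within
  groups — the latent model has no composition-heterogeneity term, and
  free Poisson composition would add ~50% spurious between-person
  variance to protein;
* every consumed group is a staple (eaten daily) by default, matching the
  one-part model's "consumed daily by all" assumption.

Ground truth records each person's latent habitual intake of every
nutrient (the person's basket nutrient-to-energy ratio times
$g^{-1}(H_i)$), which is what EAR planting (`generate_ear_table()` places
cutoffs at chosen latent quantiles) and the recovery tests check against.

What this means for interpreting green tests: the generator is a
*correct-model baseline*. Passing recovery, cut-point and coverage tests
shows the estimator does what it claims when its assumptions hold. Real
recall data have episodically consumed foods, composition heterogeneity
between persons, day-of-week and season structure, reporting error and
single-recall participants — none of which the defaults emulate, and the
lognormal portion distribution is a modelling choice, not an observed
fact. Conclusions about robustness to those features need the
misspecified variants a user can build by changing the generator
settings, not the defaults.

## Problem sizes used in validation

The shipped test-suite exercises the full default survey (1185 persons)
for the allocation-stability, conservation and direction-of-effect
checks; n = 1000 single-sex surveys for parameter recovery and EAR
cut-point fidelity; n = 4000–8000 hand-generated lognormal/normal
populations for the closed-form mean and cut-point oracles; and 200
regenerated survey worlds of 150 women with B = 200 bootstrap iterations
each for interval coverage. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping a full run of
the suite in the minutes range.

## Known limitations

* One-part model only: episodically consumed components (where a two-part
  model with a consumption-probability part is needed) are out of scope.
* Linear age trend on the transformed scale; no age-specific EARs within
  the adult range.
* Replacement probabilities are uniform within candidate lists — no
  market-share or preference weighting.
* The plant-protein share is a ratio of weighted habitual means
  (population framing), not a mean of person-level ratios; the
  alternative convention would weight low-protein consumers more.
* Footprint factors are point values; LCA uncertainty and seasonal or
  origin-specific variation are not represented.
* Population-level statements only: the model says what fraction of the
  population falls below a cutoff, not which individuals.
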