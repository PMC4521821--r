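---
title: "Methods: coupling a fuzzy expert system with a dynamic Bayesian network for grape maturity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling a fuzzy expert system with a dynamic Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgrapedbn)
```

## The problem

From veraison to harvest, the sugar concentration `S` (g/L) of grape berry
must rises and the total acidity `Ac` (g/L eq H2SO4) falls, at rates driven
by weather: temperature, insolation, rainfall and humidity. Winegrowers
sample berries weekly over the 4–5 week maturation window and must
anticipate the harvest date. Two knowledge sources coexist and neither is
sufficient alone: a few years of weekly measurements (one vintage yields one
climate trajectory, so learned models extrapolate poorly to unseen weather),
and the experts' qualitative memory of how day climate moves maturity,
which is rich but symbolic. This package implements both, and their
coupling:

* **FGRAPE** — a Mamdani-style fuzzy expert system mapping day climate to a
  per-day *index* (0–3) for each output, each index carrying a per-day
  increment in g/L;
* a discrete first-order homogeneous **dynamic Bayesian network (DBN)**
  over weekly states, with Dirichlet-smoothed conditional probability
  tables (CPTs) learnt from measurements;
* **FGRAPEDBN** — the DBN whose CPTs are enriched with transitions
  *simulated* by FGRAPE over randomly drawn climate configurations, filling
  the climate cells the measurement years never visited;
* a **Gaussian-process (GP) dynamic regression** baseline for comparison;
* a seeded synthetic data generator and a 10-fold cross-validation
  protocol with oenological error thresholds.

## The fuzzy expert model

Each of the five day-climate inputs is a linguistic variable partitioned
into overlapping terms by piecewise-linear membership functions
(`fgrape_variables()`): mean day temperature and maximal day temperature
(low / middle / high), day insolation (low / middle / high), day relative
humidity (low / high), day rainfall (low / middleminus / middleplus /
high). Interior terms are trapezoids; the end terms are shoulders with an
unbounded plateau at 1. The breakpoints are chosen so that every partition
sums to one at every input value; in particular the two-term humidity pair
shares the (70, 85)% transition band, across which "low" decays 1→0
linearly while "high" rises 0→1. This sum-to-one property is what makes
rule aggregation stable: the total activation over a complete crisp rule
base is exactly 1.

A rule constrains each variable to a set of admissible terms (disjunction
by max) and concludes one index class per output; activation is the
product t-norm across variables. Class weights are the normalized weighted
vote `P(C) = sum(alpha_j [rule j concludes C]) / sum(alpha_j)`. If no rule
fires — possible only with an incomplete user-supplied base — the neutral
"not favorable" class 1 receives weight 1 and a warning is emitted, since
the quotient is undefined at 0/0 and level 1 is the scale's limiting
neutral level.

The per-day increments attached to the four index levels are, for sugar,
−1 / +1 / +3 / +5 g/L (bad, not favorable, standard, exceptional day) and
for acidity +0.3 / 0 / −0.2 / −0.4 g/L. The weekly update adds `k` times
the sum of the seven daily defuzzified increments, where `k` is a
vintage-level adjustment fixed by expert judgement (0.8, 1, 0.9, 0.7 for
2006–2009; 1 for unknown vintages).

### Completing the rule base

Only 8 expert rules are recoverable verbatim (six printed standard-day
combinations and two in-text examples); the full base aggregates
3 × 3 × 3 × 2 × 4 = 216 crisp configurations. `complete_rule_base()`
honours the seed rules verbatim and labels the rest with an additive
favourability score — warmth and insolation favourable, rain strongly
unfavourable, extreme heat unfavourable — whose per-term values and class
cut points were calibrated once so that the policy *by itself* reproduces
every seed rule's class:

```{r policy}
fgrape_completion_policy()
```

Two genuinely open readings were settled as follows. One printed rule
lists a "middle" humidity term that does not exist in the two-term
humidity partition; it is encoded as unconstrained humidity, the closest
reading since mid-range humidity belongs partially to both terms. And the
humidity score is 0 in the policy: the printed rules force it (several
standard-day rules hold *for any* humidity while the class-1 rule also
covers both terms), so humidity influences the day index only through the
printed rules' structure, not the fill-in score. The complete 216-row base
ships as an editable tab-separated file
(`system.file("extdata/fgrape_rules.tsv", package = "fgrapedbn")`), so
domain experts can override any row; `read_rule_base()` reloads it.

## The dynamic Bayesian network

Weekly variables are discretized (`discretizer()`) into half-open bins
(last bin closed), each represented by its midpoint:

* sugar: 8 g/L bins on an edge grid containing 184 and 192 (17 bins over
  104–240 g/L, covering the 106–237 validity range);
* acidity: 0.5 g/L bins over 2.9–8.4 (11 bins);
* weekly variations: 5 g/L bins for `dS` over −14..36, 0.4 g/L bins for
  `dAc` over −2.2..0.4 (the span is not a multiple of 0.4, so the last bin
  is 0.2 wide — bounds coverage is kept rather than bin-width uniformity);
* climate: 3 equal bins each for the weekly temperature sum, insolation
  and rainfall, 2 for mean humidity.

Bin counts trade resolution against learnability: CPTs must be estimable
from a few hundred weekly transitions. Out-of-range values are clamped to
the boundary bin with a warning rather than rejected — measured values
slightly outside the nominal bounds should not abort a prediction.

The default structure (`grape_dbn_structure()`) makes the four climate
nodes roots, gives each weekly variation node `dS`, `dAc` the four climate
nodes of the same week as parents, and each level node its previous-week
level plus the same-week variation: `S(t) | S(t−1), dS(t)` and
`Ac(t) | Ac(t−1), dAc(t)`. Alternative structures can be built with
`dbn_structure()` and reuse all learning and inference code.

Parameters are expected-a-posteriori estimates under a uniform Dirichlet
prior `alpha_ijk = 1/r_i`:
`theta_ijk = (N_ijk + alpha_ijk) / sum_k (N_ijk + alpha_ijk)`.
With no data every row is exactly uniform; with abundant data the prior
washes out. During learning the variation nodes are treated as observed
(computed from consecutive measurements); at prediction they are latent.
For the first slice, nodes with temporal parents fall back to a marginal
prior (uniform unless first-week marginals are learnt); in use this slice
is always pinned by the week-1 measurement evidence, so the convention is
inert in practice but is shared consistently by the filter and the joint
probability, and exercised by the enumeration oracle in the tests.

Filtering is exact: the belief over the interface nodes (`S`, `Ac`) is
propagated through the unrolled two-slice template by variable
elimination, conditioning on each week's climate evidence as it arrives —
prediction mode, no look-ahead. State spaces are tiny, so exactness costs
milliseconds and avoids any sampling error. The posterior mean over bin
midpoints converts each weekly marginal to physical units.

## The coupling

`generate_configurations(n)` samples `n` weekly climate tuples uniformly
within the physical bounds — uniformity is a deliberate choice (the
sampling distribution is otherwise unspecified) because the purpose of the
simulated database is *coverage* of climate cells absent from the
measurement years. Each weekly tuple is decomposed into seven days
(extensive quantities divided by 7, humidity carried over, daily maxima
drawn uniformly between the day mean and the week's maximum), FGRAPE
simulates a full 5-week maturation window from a random initial state
(single transitions would never produce the level/variation co-occurrences
the level nodes need), and every simulated weekly transition is
discretized into a count record tagged `simulated`.

The update composes the simulated counts onto the experimental posterior:
with `alpha' = N_exp + alpha` already in place, the refreshed estimate is
`theta_ijk = (N_sim_ijk + alpha'_ijk) / sum_k (...)`, rows renormalized
over the full composed counts. The printed form of this update is
typographically inconsistent about its denominator; renormalizing over the
composed counts is the only reading that keeps rows summing to one and
reduces exactly to plain learning when the simulated database is empty —
both properties are asserted in the tests. Experimental and simulated
counts are kept in separate ledgers, so the update is auditable and
reversible, and the number of still-uniform ("prior-only") CPT rows can be
monitored with `prior_only_rows()`. Simulated scenarios use the neutral
`k = 1`.

## The Gaussian-process baseline

The two outputs (next week's acidity and sugar) are modelled as Gaussian
processes sharing one squared-exponential kernel
`k(xi, xj) = theta1 exp(−theta2 ||xi − xj||²)` over the six-dimensional
standardized state (acidity, sugar, and the four weekly climate
variables); standardization is required because the kernel is isotropic
and raw sugar units would dominate the distance. Each output has a linear
mean function in an intercept, a moving average of its own previous values
and the six state variables; the moving-average window defaults to the two
previous weeks. Both window and mean family are configuration knobs, not
normative: the source formulation names them only loosely. The mean
coefficients are profiled out by generalized least squares (with a tiny
ridge so exactly collinear mean columns — e.g. a week-1 moving average
equal to the state itself — stay solvable), and `(theta1, theta2)`
maximize the summed log marginal likelihood. The objective is non-convex,
so optimization restarts from 10 seeded points; a jitter ladder
(1e−10 → 1e−6) keeps the kernel matrix factorizable with duplicated
inputs. Trajectory prediction mirrors the network protocol: start from the
week-1 measurement and feed predictions forward.

## The synthetic data generator

No measurement dataset is distributable, so `generate_maturation_dataset()`
emulates the study regime: 28 parcels × 4 vintages, kinetics of 4 or 5
weekly points (3 or 4 transitions), ≈ 500 weekly observations. Daily
weather has the first-order structure that matters for the models:
autocorrelated mean temperature (AR(1), innovation sd 1.6 °C, vintage- and
parcel-level offsets) with a slow seasonal decline, maxima above means,
bursty rainfall with wet-day persistence, insolation reduced on wet days
and humidity anticorrelated with insolation, calibrated so weekly
aggregates respect the physical bounds in ≥95% of weeks. It does *not*
emulate spatial correlation between parcels, fronts/heat waves, or soil
covariates — so passing recovery tests here says the algorithms are
correct, not that the models are adequate for any particular vineyard.

Ground-truth kinetics are produced by FGRAPE itself with the vintage's
`k` (ideal for testing the DBN/coupling recovery machinery, but circular
for validating FGRAPE — an independent logistic-sugar / exponential-acid
truth mode is provided for that), plus Gaussian observation noise with
defaults σ_S = 3 g/L and σ_Ac = 0.15 g/L — roughly a third of the
acceptable-error thresholds, so that threshold checks remain a meaningful
discrimination and not a noise floor. Initial states draw from
125–160 g/L and 6.5–8.2 g/L, keeping 4-week trajectories inside the
validity bounds for typical weather.

## Validation

The cross-validation unit is the parcel-vintage kinetics: weekly points
within one kinetics are serially dependent, so splitting a kinetics across
folds would leak the trajectory into training. Folds are stratified by
vintage where possible and deterministic given the seed. Every held-out
kinetics is predicted from its week-1 measurement and its weekly climate
only; metrics are pooled RMSE and R² per output. The acceptance
thresholds are derived, not assumed: 8.5 g/L of sugar is half an
alcoholic degree at 17 g/L per degree, and the acidity threshold is 7.5%
of the scale deviation, 0.075 × (8.4 − 2.9) = 0.4125 g/L, reported to two
decimals (0.41) and compared unrounded.

```{r thresholds}
error_thresholds()
```

## Numerical choices and degenerate inputs

* Half-open bins with the last bin closed: every finite value maps to
  exactly one bin; out-of-bounds values clamp with a warning.
* The expert dynamics are never clamped to the validity bounds (bounds
  are a check, not physics); a trajectory leaving them warns once.
* Zero total rule activation falls back to the neutral class with a
  warning (see above).
* Filtering normalizes per week and raises an error on zero-probability
  evidence rather than silently renormalizing an impossible observation.
* GP: jitter ladder for degenerate kernels, ridge for collinear mean
  columns, optimizer bounds on the log scale to keep `theta > 0`.

## Problem sizes used by tests and scripts

The test suite checks the filter against brute-force enumeration on 200
random networks of up to 5 nodes, 3 states and 3 slices; CPT recovery uses
10⁴ sampled transitions (tolerance ±0.02); the end-to-end acceptance runs
at the study scale of 28 parcels × 4 vintages. `scripts/acceptance.R`
cross-validates all four models on one such synthetic dataset — these
sizes are the package's reference experiment and complete in a few
minutes on one CPU.

## Known limitations

* The published error figures of the original study were computed on a
  proprietary Loire Valley dataset that was never deposited; nothing here
  reproduces those numbers, and all quantitative results of this package
  refer to its own synthetic regime.
* Only 8 of the expert rules are public; the other 208 conclusions come
  from the completion policy and should be reviewed by domain experts via
  the shipped rule file before operational use.
* The default synthetic truth reuses FGRAPE, which flatters the expert
  model in comparisons on that data; use `truth = "logistic"` for
  non-circular FGRAPE assessment.
* Structure learning, smoothing (backward passes), continuous-node
  networks and missing-data EM are out of scope, as are anthocyanin
  prediction and berry mass.
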