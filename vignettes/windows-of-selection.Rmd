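---
title: "Windows of selection and dominance: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windows of selection and dominance: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selwin)
library(dplyr)
```

## The problem

Public-health insecticides (indoor residual sprays, treated bednets) are
deployed at high concentration and then decay over months to years. Right
after deployment the concentration may kill resistant and susceptible
insects alike; long after it, neither is killed. In between lies the
*window of selection*: the range of concentrations — equivalently, the
period of time — over which resistant insects die less than susceptible
ones, so that resistance is selected. Because insects are diploid, a
single-locus resistance gene also produces heterozygotes, and the relative
mortality of the SR genotype changes with concentration: at high doses the
heterozygote dies like the susceptible homozygote (resistance effectively
recessive), while at lower doses it survives like the resistant one
(effectively dominant). The sub-region of the selection window where
heterozygote mortality falls below SS mortality is the *window of
dominance*, and it is where selection is strongest — at low allele
frequencies almost every resistance allele sits in a heterozygote.

`selwin` quantifies these windows. It converts per-genotype bioassay
mortalities into the standard inputs of single-locus resistance models,
computes the per-generation selective advantage of the resistance allele
and the number of generations until resistance reaches a threshold
frequency, and detects and measures windows on observed (or synthetic)
mortality curves.

## The selection model

Let $p$ be the resistance (R) allele frequency and $q = 1 - p$. Each
discrete generation starts at Hardy–Weinberg proportions $p^2 : 2pq : q^2$
(random mating, no demography). A fraction $x$ of the population is
exposed to the insecticide; exposed genotypes survive with probabilities
$w_{rr}, w_{sr}, w_{ss}$ (fitness = 1 − mortality), and the unexposed
fraction survives regardless of genotype — there are no fitness costs of
resistance in this model. The next-generation frequency is

$$
p' \;=\; \frac{x\,(p^2 w_{rr} + pq\,w_{sr}) + (1-x)\,(p^2 + pq)}{\bar W},
$$

where $\bar W$ is the total surviving allele mass (the sum of the $p'$ and
$q'$ numerators), so $p' + q' = 1$ by construction. At $x = 1$ this is the
textbook diploid viability-selection recursion. The per-generation
*selective advantage* is $z = p'/p - 1$: zero exactly when selection is
absent, and frequency-dependent, because $p$ sets how many R alleles are
carried by heterozygotes.

Bioassay mortalities map onto three standard simulation inputs:

* **effectiveness** — SS mortality under exposure;
* **restoration** — the share of SS mortality prevented in RR,
  $(m_{ss} - m_{rr})/m_{ss}$, defined as 0 when $m_{ss} = 0$ (there is no
  mortality to prevent, and this avoids a 0/0 outside the window of
  selection);
* **dominance** $h = (m_{ss} - m_{sr})/(m_{ss} - m_{rr})$ — the position
  of the heterozygote between the homozygotes; 0 is fully recessive
  resistance, 1 fully dominant.

Dominance is undefined where $m_{ss} \le m_{rr}$ (the window is shut, or a
fitness-cost regime that this package flags but does not model). Observed
heterozygote mortalities that fall outside the $[m_{rr}, m_{ss}]$ envelope
— routine measurement noise at some grid points — are clamped into
$[0, 1]$ and flagged rather than treated as fatal. Reciprocal heterozygote
arms (SR and RS from the two cross directions) are averaged with an
unweighted arithmetic mean before any of this.

A *time to resistance* is the number of generations for $p$ to rise from a
starting frequency $p_0$ to a threshold (default 50%), iterating the
recursion with the mortalities held constant; runs that do not arrive
within the cap (default 500 generations) are **censored** and carried
explicitly as `">500"`, never as a bare number, through every profile and
report downstream.

### Default parameterization

| parameter | default | meaning |
|---|---|---|
| `x` | 0.3 | proportion of the population exposed each generation |
| `p0` | 0.01 and 1e-4 | illustrative starting R-allele frequencies |
| `threshold` | 0.5 | allele-frequency endpoint of the simulation |
| `max_generations` | 500 | censoring cap |
| `span` | 0.75 | loess span for curve smoothing |
| `delta` | 0 | minimum mortality difference for a window to count as open |

These are the standard study conditions for this class of model; all are
overridable per call or via `run_config()`. A single exposure applies to
all individuals — the model does not distinguish sexes, which would add
structure without changing any quantity computed here.

## Window detection

A mortality curve is a tidy table of per-arm mortality along a strictly
monotone concentration or time axis. Detection compares a susceptible arm
with a resistant one (strains R/S, or the SS and RR genotype arms): the
window of selection is open wherever `mort_S - mort_R > delta`, and the
window of dominance wherever additionally `mort_SS - mort_SR > delta`,
which makes the dominance window a subset of the selection window by
construction. Boundaries are located by linear interpolation of the
mortality difference between adjacent grid points, on the log10 axis for
concentrations (bioassay series span decades) and the linear axis for
time. Windows that are already open at the first observed point, or still
open at the last, are marked open-ended, and their boundary is the
observed bound rather than a crossing.

Detection runs by default on loess-smoothed series (locally weighted
linear regression, tricube weights, evaluated at the original grid and
clipped to [0, 1]) because raw bioassay replicates cross erratically; a
`smooth = FALSE` flag gives raw-series detection, and both modes are
legitimate since published boundary values do not state which series they
were read from.

Numerical and degenerate-input choices:

* `delta` defaults to 0 with a strict inequality. On *exact* sigmoid
  curves with floor 0 and ceiling 1, however, the arms differ by some
  positive amount everywhere, so a strict-zero rule never closes a window.
  For analyses of the package's idealized scenario we therefore use
  `delta = 0.01` — one percentage point, below the resolution of any real
  bioassay — as the operational definition of "no meaningful difference".
* Noisy curves can open several disjoint runs; the report covers the
  maximal spanning window and sets a `fragmented` flag, since the
  windows-of-selection framework assumes one contiguous window.
* The fold-range of a concentration window is `max(boundary) /
  min(boundary)`, always ≥ 1 and invariant to which boundary is labelled
  "opening". Reports state boundaries in deployment order — high to low
  concentration, early to late time — because that is the order a decaying
  deployment traverses them.
* Missing observations can be filled with `complete_curve()` under
  explicit per-arm extrapolation rules (constants 0 or 1 over a stated
  axis region, closed intervals); rules never overwrite observed data —
  an overlap is an error, not a silent preference.
* Arms with fewer than 4 observed points are passed through the smoother
  unchanged, with a warning.

Smoothing trades noise against curvature bias: a loess span suited to a
gently curving series will flatten a very steep sigmoid, so RMSE
improvement against the generating curve is only guaranteed when the noise
dominates that bias (the test suite checks exactly this regime — small
replicates on a gentle slope). For steep curves, prefer raw-series
detection or a smaller span.

## The synthetic-data generator

No laboratory data ship with the package; every analysis stage is
exercised against generated data whose statistical structure matches what
the analysis assumes:

* **Dose–response.** Per-arm log-logistic (Hill) mortality
  $m(c) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor}) / (1 +
  (\mathrm{LC}_{50}/c)^{\beta})$ — the standard bioassay model on a log
  concentration scale (a probit alternative is deliberately out of
  scope). With equal slopes and LC50s ordered RR > SR > SS, the induced
  dominance rises from ≈0 at high concentration toward 1 as concentration
  declines, which is the geometry that nests a dominance window inside the
  selection window.
* **Sampling.** Binomial dead counts per replicate (`sample_bioassay()`),
  seeded and leaving the session RNG untouched. Fitting the floor-0 /
  ceiling-1 model to counts is exactly a binomial GLM on log
  concentration, which is how `fit_dose_response()` recovers LC50 and
  slope.
* **Decay.** First-order exponential decay
  $c(t) = c_0 2^{-t/t_{1/2}}$, the conventional residual-insecticide
  model, maps time-after-deployment onto the concentration axis. It is a
  scenario generator, not a fitted claim about any particular product.
* **Scenarios.** `scenario_curves()` provides three cases over a shared
  SS/RR envelope (LC50 0.01 and 1.0 assay units, slope 3, floor 0,
  ceiling 1): *best* (heterozygote glued to SS, dominance constant 0, no
  dominance window), *worst* (glued to RR, dominance constant 1) and
  *intermediate* (own LC50 0.1, dominance transitioning 0 → 1 as
  concentration declines). The envelope constants are package fixtures
  chosen so the selection window spans roughly two decades with the
  dominance window inside it; they emulate the published idealized
  geometry but are not claimed to match any archived curve numerically.
  The default analysis grid is 29 log-spaced points over $10^{-5}$ to
  $10^{2}$ assay units — wide enough that both homozygote curves saturate
  at each end, fine enough (4 points per decade) that window boundaries
  and profile extrema are resolved to well under half a decade.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: substrate chemistry (cement/mud/wood release
insecticide differently), control-mortality correction, drift in colony
health over long experiments, overdispersion beyond binomial sampling, and
multi-locus or polygenic resistance.

## Verification strategy

The test suite checks the recursion against an independent brute-force
oracle that enumerates the six population masses (exposed/unexposed ×
three genotypes), applies survival and counts alleles — agreement is at
the 1e-12 level over 1e5 random draws, with the textbook formula recovered
at full exposure. Time-to-resistance values are compared with a
hand-iterated version of the same enumeration. Window boundaries are
compared with a 1000-point dense-grid scan of the generating functions,
required to agree within one observation-grid step. Parameter recovery is
checked over 200 seeded synthetic experiments (10 concentrations × 20
replicates × 100 exposed), with LC50 recovered within ±20% and slope
within ±30% in at least 95% of them. These problem sizes resolve every
property being tested while keeping the default suite fast.

## Known limitations

* Single locus, two alleles; polygenic resistance generates analogous
  windows but is not modelled.
* No fitness costs: where resistant mortality exceeds susceptible at low
  concentration, the package flags the point (dominance undefined) but
  does not quantify selection back toward susceptibility.
* No demography, dispersal, competitive release, or disease-transmission
  consequences — the model tracks allele frequencies only.
* Window boundary estimates carry no confidence intervals; they are
  deterministic functions of the (possibly smoothed) series.
* Concentration units are opaque strings: bioassay series mixing percent
  papers, ppm and discriminating-dose multiples are never converted.

## A worked pass through the pipeline

```{r pipeline}
cur <- idealized_scenario()
detect_selection_window(cur, delta = 0.01, smooth = FALSE)
detect_dominance_window(cur, delta = 0.01, smooth = FALSE)

prof <- resistance_time_profile(cur, p0 = 1e-4)
filter(prof, !censored) |> slice_min(generations, n = 3)
```

The fastest times to resistance fall inside the window of dominance, and
every grid point outside the window of selection is censored at the
500-generation cap — the geometry that makes declining concentrations,
not peak doses, the engine of resistance evolution.
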