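---
title: "Size-age stock assessment: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-age stock assessment: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeage)
```

`sizeage` implements the complete size-age assessment chain used for
data-limited river salmonid populations: length-weight allometry, growth
trajectory selection, catch-curve mortality, length-based reference
points, and harvest-regulation evaluation. This vignette documents the
models, every tunable that matters, and the places where we had to make a
judgement call.

## The data model

A survey is a flat table of individual captures: total length `TL` (cm),
wet mass `W` (g, possibly missing), fractional age (years, possibly
missing), gear (`electrofishing`, `angling`, `trolling`), river tract,
year, an optional transect id (electrofishing only) and an optional
`recapture_of` link for pit-tagged fish caught more than once.

Three analysis subsets are drawn from one table, mirroring how such
surveys are actually used: `TL_W` (measured, non-imputed masses) for the
allometry; `TL_Age` (aged fish) for growth and mortality; `DENS`
(electrofishing records on a known transect) for density. Age classes are
one-year intervals *excluding their lower limit* — class *k* covers
ages in (*k*, *k*+1], so a fish aged exactly 1.0 year is in class 0.
Ages are stored fractional and binned lazily, never rounded in place.

Recaptured individuals are collapsed to a single record. The convention
here is to keep the *earliest* capture: it is the least
growth-confounded measurement of that individual. Survey reports rarely
state which capture entered their analyses; this is our documented choice,
applied identically everywhere.

## Length-weight allometry

`fit_length_weight()` estimates `log10(W) = b·log10(TL) + log10(a)` by
ordinary least squares, base-10 throughout (the convention of fisheries
length-weight tables). Missing masses are imputed by the raw
back-transform `10^(b·log10(TL) + log10(a))` with **no lognormal
bias-correction factor**: when the purpose of imputation is to fill
individual records that feed biomass totals in a standardized report, the
raw inverse is what the field uses, and applying a smearing correction
would make the imputed records inconsistent with the printed regression.
Imputed masses are flagged (`W_imputed`) and excluded from any refit,
which prevents the regression from feeding on its own predictions.

## Growth trajectories and model selection

Three families are fitted to length-at-age by nonlinear least squares
(Levenberg-Marquardt, `minpack.lm`): von Bertalanffy
`TL_inf(1 − e^{−K(t−t0)})`, Gompertz `TL_inf·e^{−e^{−G(t−t0)}}` and
logistic `TL_inf/(1+e^{−G′(t−t0)})`. The two sigmoid families inflect at
`t0`; for the Gompertz curve the length there is `TL_inf/e` and the slope
is the absolute maximum growth rate `AMGR = G·TL_inf/e` (cm/yr). AMGR is
always reported from the unrounded fitted parameters — recomputing it
from a rounded table row can shift the last digit.

Starting values are data-driven and reproducible rather than
hand-supplied: `TL_inf⁰ = 1.1 × max(TL)`, `t0⁰ = median(age)`, and the
rate from the slope of the family's own log-linearisation (e.g.
`log(−log(TL/TL_inf⁰))` against age for Gompertz). Convergence tolerances
are `ftol = ptol = 1e−10` with at most 500 iterations; a non-converged
fit is returned flagged, not silently dropped.

Model selection uses AICc with **k = 4** — three curve parameters plus
the Gaussian error variance — computed from the full log-likelihood:
`AICc = −2·logLik + 2k + 2k(k+1)/(n−k−1)`. Akaike deltas and weights are
invariant to the additive constant in the likelihood, so this matches
selection done with RSS-based shortcuts. Parameter intervals are
`estimate ± t·s.e.` with df = n − 3.

Von Bertalanffy fits on sigmoid data routinely escape to biologically
impossible asymptotes. Such fits are *reported with a warning* (default
plausibility bound 140 cm, roughly the species-record scale for very
large river trout, configurable) rather than suppressed: the comparison
table should show why the family lost.

Because upper age classes are often sparse or gappy, a leave-out-largest
sensitivity refit (`sensitivity_refit()`, default dropping the 3 longest
fish) reports the relative change in `TL_inf`, with the conventional 10%
robustness threshold.

## Catch-curve mortality

`build_catch_curve()` tabulates catch per age class (keeping internal
zero classes visible). The descending limb by default *excludes* the peak
(first fully recruited) class, is truncated at an optional `max_class`,
and always stops before the first empty class after its start — classes
beyond a gap cannot support the constant-Z reading and a handful of very
old stragglers would otherwise dominate `T`.

On recoded ages `x = class − first included class`, annual survival is
the Chapman-Robson statistic `S = T/(n+T−1)` with `T = Σx`. This is the
*unbiased* estimator of the geometric survival parameter; it differs
from the maximum-likelihood estimate `T/(n+T)` by `T/((n+T)(n+T−1))`,
which the test suite pins exactly and which vanishes by n in the
thousands. Instantaneous total mortality is `Z = −ln(S)` minus the
small-sample bias correction `(n−1)(n−2)/(n(T+1)(n+T−1))`; the
uncorrected version is exposed via `correct = FALSE`. The correction is
strictly positive, so corrected Z is always below `−ln(S)`.

Two variance conventions are implemented, because the literature is not
unanimous and published tables are not always reproducible from any
single one:

* `variance = "chapman_robson"` (default): the estimator's classical
  unbiased variance `var(S) = S(S − (T−1)/(n+T−2))`, carried to Z by the
  delta method `se(Z) = se(S)/S`. In our simulations (geometric
  catch-at-age, limb sizes 80–500) its normal 95% intervals cover the
  generating Z at 0.948–0.961 — this is the variant whose intervals mean
  what they say, and the one the acceptance suite's coverage check runs.
* `variance = "binomial"`: `var(S) = S(1−S)/(n−2)`, a binomial-style
  approximation present in some assessment tooling. It reproduces certain
  published standard errors exactly but over-covers (~0.99) in the same
  simulations; use it only to match reports computed that way.

The rest of the chain is arithmetic: `A = 1 − e^{−rate}` converts any
instantaneous rate to an annual proportion; natural mortality comes from
the one-parameter longevity estimator `M = 5.109/t_max`; fishing
mortality is `F = Z − M` and the exploitation ratio `E = F/Z`, with
`E = 0.5` exactly when `F = M` (the classical optimal-yield heuristic).
When the empirical `M` exceeds the estimated `Z` — perfectly possible
with a borrowed `t_max` — `F` is floored at zero with a warning and an
explicit flag, rather than reporting a negative fishing mortality.

## Length-based reference points

Mean length at first maturity and optimum length come from published
cross-species log-linear relations on the asymptotic length:
`log10(TL_m) = 0.8979·log10(TL_inf) − 0.0782` (residual s.e. 0.127) and
`log10(TL_opt) = 1.0421·log10(TL_inf) − 0.2742` (s.e. 0.073). Their 95%
prediction intervals exponentiate `log10(point) ± c·s.e.`. The source
regressions' sample sizes are not published, so their df is unknown; we
default to `df = Inf` (c = 1.96), which is both the natural choice for a
large cross-species compilation and the one that reproduces the familiar
printed interval scale. `df` is configurable on every
`empirical_relation()`.

The optimum harvest slot is `TL_opt ± 10%`, and the megaspawner
threshold is fixed at the slot's upper bound `1.1·TL_opt`: fish above it
are the large, disproportionately fecund individuals a slot is designed
to protect.

## Harvest-policy evaluation

`classify_catch()` applies a minimum-length limit (retainable when
`TL ≥ MLL`) or a harvest slot (retainable inside `[lower, upper]`,
bounds inclusive — regulations are phrased inclusively, and ties at a
measured centimetre must fall somewhere deterministic). Retained fish are
partitioned into `immature` (`TL < TL_m` point estimate), `within_slot`,
and `mature_outside_slot`; the megaspawner flag overlaps the last
category and is reported separately, so the three categories always sum
to the retained count. Classifying at the prediction-interval bounds
instead of the point estimate is available by passing a
`reference_points()` built from a shifted relation. Length-frequency
reporting uses left-closed 1-cm bins `[k, k+1)`.

## Density

Electrofishing sweeps sample ~2 m³ of water per surveyed metre, so a
transect of length `L` m samples `2L` m³. Numerical density is catch per
volume; biomass density uses measured masses plus imputed ones (counted
and reported per transect). Between-tract comparisons use the
Kruskal-Wallis test with pairwise Wilcoxon rank-sum tests under
Bonferroni correction; midranks handle ties, and the exact null is used
only when every group has fewer than 20 observations and no ties
(beyond that the normal approximation is standard and indistinguishable).

## The synthetic population generator

`simulate_population()` generates data with exactly the structure the
estimators assume, so that every stage is testable without field data:

* integer age classes geometric with survival `e^{−Z}`, truncated at
  `t_max`, thinned below the fully recruited age by per-class relative
  catchabilities, plus a uniform (0, 1] fractional offset (which makes
  the right-closed binning recover the drawn class exactly);
* lengths Gompertz-mean with additive Gaussian noise (the error model of
  the nonlinear fits), redrawn when non-positive;
* masses from the allometric power law with lognormal noise (the error
  model of the log-scale regression), a fixed fraction deleted.

Defaults mirror the study conditions of a large-river marble trout
population: n = 295 aged fish, Z = 0.924/yr, t_max = 11 yr, full
recruitment at class 2 with ascending catchabilities (0.2, 0.6), Gompertz
(105.0 cm, 0.216/yr, 3.99 yr), allometry (a = 10^−2.100, b = 3.055), and
27% missing masses. Two residual scales are not printed in typical
reports and were fixed once at field-realistic values: `sigma_TL = 5` cm
(length-at-age scatter of river salmonids spanning 6–85 cm) and
`sigma_logW = 0.07` (consistent with an adjusted r² ≈ 0.99 at these
length ranges). One seeded PRNG stream per dataset makes every draw
bit-reproducible.

What the generator deliberately does *not* emulate: spatial structure and
movement, multi-year cohort dynamics, size-selective angling within the
recruited classes, and measurement error in age determination. Passing
tests therefore validate the estimators under their own assumptions —
they do not certify those assumptions for any particular river.

## Problem sizes and numerical conventions

The test suite exercises: exact recovery on noiseless data (tolerance
1e−6); slope recovery at n = 5000; parameter-CI coverage over 60
replicates of n = 800; catch-curve CI coverage over 200 replicates of
limb size 500; and a likelihood-grid oracle at n = 3000 with a 1e−5
grid. These sizes were chosen so each check is statistically decisive at
the asserted tolerance while the whole suite stays interactive.

Human-readable report output rounds half-up at 3 decimals (`0.4595…`
prints as `0.460`, matching how assessment tables are typeset); machine
formats (JSON) always carry full precision, and two renders of the same
report are byte-identical.

## Known limitations

* The catch curve inherits all classical assumptions: closed population,
  constant recruitment and vulnerability, constant Z on the limb. The
  package checks none of them against the data; it documents them.
* `M = 5.109/t_max` borrows a cross-species longevity relation; with an
  uncertain `t_max` the downstream `F` and `E` shift accordingly, and no
  uncertainty from `M` is propagated into them.
* Reference points are cross-species empirical predictions from
  `TL_inf`, not local maturity observations; their prediction intervals
  are wide and should be read as such.
* One pooled allometry is fitted (no tract- or year-specific curves), and
  growth is purely cross-sectional (no individual or seasonal effects).
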