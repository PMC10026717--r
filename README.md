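# sizeage

Size-age population assessment for inland trout fisheries.

Many river salmonid populations — here, the motivating case is an
introgressed marble trout (*Salmo marmoratus*) population in a large
Alpine river — are managed with almost no stock-assessment data: a few
years of electrofishing and angling surveys, lengths for everyone, masses
and scale-read ages for some. `sizeage` turns exactly that kind of table
into a complete, reproducible assessment:

1. **Allometry** — `log10(W) = b·log10(TL) + log10(a)` by OLS, with
   flagged imputation of missing masses through the raw back-transform.
2. **Growth** — von Bertalanffy, Gompertz and logistic length-at-age
   trajectories by Levenberg-Marquardt nonlinear least squares, compared
   by AICc (k = 4), with AMGR = G·TL_inf/e and a leave-out-largest
   sensitivity refit.
3. **Mortality** — catch-at-age curve, descending-limb selection, the
   unbiased Chapman-Robson estimator S = T/(n+T−1) with bias-corrected
   Z = −ln S − (n−1)(n−2)/(n(T+1)(n+T−1)), the longevity estimator
   M = 5.109/t_max, and the partition F = Z − M, E = F/Z with annual
   rates A = 1 − e^(−rate).
4. **Reference points** — TL_m and TL_opt from published empirical
   relations on TL_inf, with 95% prediction intervals, the optimum
   harvest slot TL_opt ± 10% and the megaspawner threshold 1.1·TL_opt.
5. **Harvest policies** — minimum-length limits vs harvest slots
   evaluated against the angling length-frequency: who could be
   retained, and how many of those never reproduced.
6. **Density** — numerical and biomass density per electrofishing
   transect (volume = 2L m³), with Kruskal-Wallis / pairwise Wilcoxon
   (Bonferroni) comparisons between river tracts.

Everything is tidyverse-shaped: capture tables in, tibbles out,
`tidy()`/`glance()` methods on every fitted object, `autoplot()` for the
fits and curves, and a seeded synthetic-population generator
(`simulate_population()`) that reproduces the statistical structure the
estimators assume, so the whole chain is testable offline.

## Worked example

Reference points straight from an asymptotic length:

```r
library(sizeage)
reference_points(105.0)
#> Reference points from TL_inf = 105.0 cm
#>   TL_m   = 54.529 cm (PI 30.7, 96.7)
#>   TL_opt = 67.933 cm (PI 48.9, 94.4)
#>   slot   = 61.1-74.7 cm, megaspawners > 74.7 cm
```

A fish with TL_inf ≈ 105 cm matures on average at ~54.5 cm, yields most
at ~68 cm, and the recommended retention window is ~61–75 cm; fish above
~75 cm are megaspawners that a slot protects.

The full chain on a synthetic survey (2,000 fish drawn from the default
study conditions — Z = 0.924/yr, Gompertz (105 cm, 0.216/yr, 3.99 yr),
allometry (10^−2.100, 3.055)):

```r
rep <- run_full_assessment(config = synthetic_config(n = 2000, seed = 7))
rep
#> Size-age population assessment
#> records: 2000
#>
#> Length-weight: log10(W) = 3.059 log10(TL) -2.105 (adj r2 0.992, n 1471)
#> Growth [gompertz]: TL_inf 111.830 cm, rate 0.205 /yr, t0 4.286 yr (n 2000)
#> Sensitivity (-3 largest): TL_inf 107.002 cm, change 4.318%, pass
#> Mortality: S 0.400  Z 0.915 (CI 0.847, 0.984)  A_Z 0.600
#>            M 0.464  A_M 0.372  F 0.451  A_F 0.363  E 0.493
#> Reference:  TL_m 57.703 cm (PI 32.530, 102.357)
#>             TL_opt 72.544 cm (PI 52.182, 100.851), slot 65.290-79.799 cm
#> Harvest policies:
#>   MLL 35 cm: retained 41/417 (0.098), immature 0.878 of retained
#>   MLL 40 cm: retained 25/417 (0.060), immature 0.800 of retained
#>   HS 60-70 cm: retained 4/417 (0.010), immature 0.000 of retained
#> Warnings:
#>   Fitted TL_inf (4050.4 cm) exceeds the plausibility bound of 140 cm.
```

Reading it: the Gompertz family wins the AICc comparison (the von
Bertalanffy asymptote escapes to 40 m and is reported with a warning,
not hidden); the catch curve recovers Z ≈ 0.92/yr, so ~60% of the
population dies each year, about half of that from fishing (E ≈ 0.49);
and under a 40-cm minimum-length limit 80% of the retainable catch is
immature — the overfishing signal a harvest slot is designed to remove.
Real data enter the same way via `read_fish_table("survey.csv")` and
`run_full_assessment(data = fish, transects = transects)`.

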