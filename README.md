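# hospgrowth

Decomposition of annual growth in hospital activity into demographic,
health-status and residual components.

## What it does, and for whom

Health-system planners need to know *why* hospital activity grows: more
people, older people, sicker people at a given age, or everything else
(supply, policy, practice). For analysts working with counts of hospital
activity by year, single year of age and sex — admissions (elective,
non-elective, maternity), outpatient attendances and type-1 emergency
department attendances — this package estimates the multiplicative
decomposition

```
G = (1 + P)(1 + S)(1 + H)(1 + R) − 1
```

where G is total annual growth, P growth attributable to population
size, S to the age–sex structure, H to age-specific health status and R
the residual.

The components are identified by a ladder of nested negative-binomial
spline regressions of cell counts on calendar year:

| model | linear predictor |
|---|---|
| M1 | `β₁·year` |
| M2 | `β₂·year + offset(log population)` |
| M3 | `β₃·year + s(age, by = sex) + offset(log population)` |
| M4 | `β₄·year + s(health_status_age, by = sex) + offset(log population)` |

so that `G = exp(β₁)−1`, `P = exp(β₁−β₂)−1`, `S = exp(β₂−β₃)−1`,
`H = exp(β₃−β₄)−1`, `R = exp(β₄)−1`, and the components multiply back to
G identically. *Health-status age* is chronological age adjusted by the
change since baseline in Sullivan-method disability-free life expectancy
(prevalence of a Cambridge Multimorbidity Score > 1.5 weighting the
life-table person-years), scaled by the relative change in life
expectancy. G and R get Wald intervals; the coefficient-ratio components
P, S, H get seeded Monte-Carlo intervals.

The package also ships a synthetic-data generator (growing, ageing
population; improving Gompertz mortality; drifting logistic morbidity;
NB activity counts) with known ground-truth components, and record-level
ingest filters (admission-method classification, attendance-status /
department-type / residency / age-sex exclusions, 90+ lumping) with a
per-rule audit trail. See the vignette in `vignettes/` for the model,
assumptions and design choices.

## Worked example

Simulate nine years of elective-style activity with known truth
(P = 1%/yr, S = H = 0, R = 2%/yr), then fit and decompose:

```r
library(hospgrowth)

cfg <- generator_config(pop_growth_rate = 0.01, ageing_drift = 0,
                        prevalence_params = list(drift = 0),
                        residual_rate = 0.02, seed = 11)
pop    <- generate_population(cfg)
life   <- generate_life_tables(cfg)
prev   <- generate_prevalence(cfg)
hsa    <- build_hsa_table(life, prev, baseline_year = 2011)
counts <- generate_activity_counts(cfg, pop, "elective")

fit <- pod_growth(counts, pop, hsa, n_sims = 1000, seed = 1)
fit
#> Hospital activity growth decomposition -- elective (2011-2019, 1638 cells)
#> Growth decomposition: elective
#>   G = 3.11% (2.13% to 4.11%) [wald]
#>   P = 1.26% (-0.42% to 2.88%) [monte_carlo]
#>   S = -0.08% (-1.39% to 1.34%) [monte_carlo]
#>   H = -0.04% (-0.90% to 0.81%) [monte_carlo]
#>   R = 1.95% (1.33% to 2.57%) [wald]

ground_truth(cfg)
#> Ground truth (elective): G=3.02% P=1.00% S=0.00% H=0.00% R=2.00%
```

Reading the output: estimated total growth is 3.11%/yr against a true
3.02%; the population component (1.26%, truth 1.00%) and residual
(1.95%, truth 2.00%) are recovered within their intervals, and the
structure and health components — truly zero here — have intervals
covering zero. `coef(fit)`, `confint(fit)`, `summary(fit)`, `plot(fit)`
and `simulate(fit)` give programmatic access; `run_pipeline()` drives
all five points of delivery end-to-end from a configuration and writes
`results.csv`, a report table and a JSON manifest.

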