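---
title: "Decomposing growth in hospital activity: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing growth in hospital activity: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Counts of hospital activity — elective, non-elective and maternity
admissions, outpatient attendances, type-1 emergency-department (ED)
attendances — grow from year to year for a mixture of reasons: there are
more people, the people are older, their age-specific health differs, and
everything else (supply, policy, clinical practice, unmet need). This
package estimates how much of the annual growth in each activity stream
("point of delivery", POD) is attributable to each of those causes, using
the multiplicative decomposition

$$G = (1 + P)(1 + S)(1 + H)(1 + R) - 1,$$

where \(G\) is total annual growth, \(P\) growth due to population size,
\(S\) due to the age–sex structure, \(H\) due to age-specific health
status, and \(R\) the residual.

The components are identified by a ladder of nested negative-binomial
(NB) regressions of the cell counts \(y_{ast}\) (age \(a\), sex \(s\),
calendar year \(t\)) on a linear year term:

| Model | Linear predictor |
|---|---|
| M1 | \(\beta_{1} t\) |
| M2 | \(\beta_{2} t + \log N_{ast}\) (offset) |
| M3 | \(\beta_{3} t + f_s(a) + \log N_{ast}\) |
| M4 | \(\beta_{4} t + f_s(\tilde a_{ast}) + \log N_{ast}\) |

with \(N_{ast}\) the mid-year population of the cell, \(f_s(\cdot)\) a
per-sex spline smooth, and \(\tilde a\) the *health-status age* defined
below. Each rung absorbs one more driver, so ratios of the exponentiated
year coefficients telescope into the components:

$$G = e^{\beta_1}-1,\quad P = e^{\beta_1-\beta_2}-1,\quad
S = e^{\beta_2-\beta_3}-1,\quad H = e^{\beta_3-\beta_4}-1,\quad
R = e^{\beta_4}-1,$$

and \((1+P)(1+S)(1+H)(1+R)-1 = e^{\beta_1}-1\) holds *identically*, for
any coefficient values — the decomposition cannot fail to add up. The
key assumptions are that the year effect is log-linear (a single annual
growth rate per rung over the study window), that the age–sex rate
profile is smooth, and that counts are NB-distributed around the cell
mean (variance \(\mu + \phi\mu^2\)).

Maternity activity is restricted to females aged 15–49; the sex smooth
is dropped there, and — because health-status age only differs from
chronological age at 55+ — M4 is undefined: H is disregarded (reported
as 0 with no interval) and R is taken from M3, the deepest defined
model. This last choice is worth flagging: whatever signal M4 would have
absorbed stays in the maternity residual.

## Health-status age

To let the model see *changes in health at a given age*, the M4
covariate replaces chronological age \(i\) with

$$\tilde a_{i,y} = i - \left(\mathrm{dfle}_{i,y} - \mathrm{dfle}_{i,y_0}\right)
\frac{\mathrm{le}_{i,y} - \mathrm{le}_{i,y_0}}
     {\mathrm{le}_{65,y} - \mathrm{le}_{65,y_0}},$$

computed per sex, with \(y_0\) the baseline year. \(\mathrm{le}\) is
period life expectancy from the life table and \(\mathrm{dfle}\) is
disability-free life expectancy from the Sullivan method: person-years
in each life-table interval are weighted by the proportion free of major
illness, here operationalised as a Cambridge Multimorbidity Score (CMS)
below 1.5,

$$\mathrm{dfle}(i) = \frac{\sum_{x \ge i} L_x\,(1 - p_x)}{l_i}.$$

In the baseline year, and at all ages below 55, health-status age is
defined to equal chronological age; if people at 55+ are living longer
*and* healthier, their health-status age falls below their actual age,
and M4 attributes the corresponding activity change to H.

Numerical choices here:

* **Open age group.** Everyone 90+ is carried at integer age 90; the
  age-90 person-years column \(L_{90}\) absorbs the whole open interval,
  so \(e_x = \sum_{t\ge x} L_t / l_x\) is exact on the tabulated grid.
* **Zero-denominator guard.** When life expectancy at the reference age
  65 has not changed since baseline (|Δ| below `guard_tol`, default
  1e-9 years), the scaling bracket is set to 1 rather than dividing by
  ~0, so the dfle signal is retained; activations are counted in the
  output's `guard_events` attribute. The reference age is exposed as
  `ref_age` — 65 is the conventional anchor, but nothing in the
  machinery depends on it.
* **Prevalence is used as-is** (year-stratified sample estimates, no
  age smoothing); a 3-age moving-average smoother exists behind
  `smooth_prevalence = TRUE` but is off by default.
* **No clamping.** Health-status ages are real-valued and may exceed 90
  or fall between integers; the spline basis domain covers the observed
  range.
* A note on reading the formula: the bracketed life-expectancy ratio
  *multiplies* the dfle difference ("relative to changes in overall
  life expectancy"); the alternative reading (dividing by the ratio) is
  deliberately not implemented.

## Fitting

The default engine is `mgcv::gam(family = nb(), method = "REML")`: a
penalised thin-plate smooth per sex (basis dimension `basis_df = 10`),
dispersion estimated by ML, the year coefficient unpenalised, with
convergence tolerance 1e-8 and up to 200 iterations. The standard error
of the year coefficient comes from the observed information with the
smoothing parameters treated as fixed — standard GAM practice, and a
known (mild) approximation. An unpenalised fallback (`method = "ns"`,
natural cubic B-splines, `df` capped at 6, fitted by `MASS::glm.nb`) is
provided; the estimand is the year coefficient, not the smooth shape,
and the test suite checks that the two engines and a range of basis
dimensions move it by far less than one standard error. Cells with zero
population are dropped (their log offset is undefined) with a logged
message; ages 90+ enter the spline as numeric 90.

## Confidence intervals

G and R are identified by a single coefficient each, so their 95%
intervals are Wald intervals \(e^{\beta \pm 1.96\,\mathrm{se}} - 1\).
P, S and H are ratios of coefficients from two different models; their
intervals are Monte-Carlo: each \(\beta\) is drawn independently from
\(\mathcal N(\hat\beta, \mathrm{se}^2)\) (1,000 draws by default, seeded
and reproducible), the component is formed per draw, and the empirical
2.5% / 97.5% quantiles are reported. Central estimates remain the
algebraic ones.

The independence of the draws is a deliberate approximation, kept
because it is how the procedure is defined: the four models are fitted
to the *same* data, so their year coefficients are in fact strongly
positively correlated, and the variance of a difference
\(\beta_a - \beta_b\) is substantially smaller than
\(\mathrm{se}_a^2 + \mathrm{se}_b^2\). The consequence, which the test
suite measures directly by refitting the ladder over hundreds of
simulated replicates, is that the P/S/H intervals are conservative —
their empirical coverage of the true component is essentially 100%,
well above the nominal 95%. Treat those intervals as honest upper
bounds on uncertainty, not as calibrated probability statements.

## The synthetic-data generator

The real study-scale inputs are restricted national datasets, so the package
carries a generative model with known ground truth against which every
stage is validated:

* **Population**: a fixed smooth age density (working-age bulk plus an
  older-cohort bump), shifted older by `ageing_drift` years per calendar
  year and scaled to grow at `pop_growth_rate`; ages above 90 lumped
  into 90+. Deterministic.
* **Mortality**: Gompertz hazards \( \lambda e^{\gamma a} \), male
  hazards a fixed multiple of female, improving by a constant proportion
  per year; full \(l_x, L_x, e_x\) columns are produced (the published
  life-expectancy products alone would not support Sullivan's method,
  which needs the person-years column).
* **Morbidity**: prevalence of CMS > 1.5 following a logistic curve in
  age, shifted older by `drift` years per year (positive = healthier),
  observed with binomial noise from 20,000 sampled records per year
  allocated to cells proportional to population.
* **Activity**: NB counts around population × rate, the log rate
  holding a per-POD age–sex curve, a calendar trend (`residual_rate`,
  the true R) and, at ages 55+, the same horizontal age displacement as
  the prevalence curve — so the health-status-age covariate can, by
  construction, absorb it.

Defaults emulate England 2011–2019 at national scale: ~53M people
growing at 0.73%/yr, mean age ~39.3 rising ~0.11 yr/yr, life expectancy
~82 (F) / ~78 (M), prevalence ~9.7% (F) / ~7.3% (M), per-capita activity
rates matching the headline POD volumes, NB dispersion 0.1. True P and
R equal their parameters exactly; true S and H depend on the POD's rate
curve and are computed numerically from the generator's mean surfaces
(`ground_truth()`), with the product identity defining true G. The
product form is itself an approximation on the generator side: ageing
and health shifts interact multiplicatively only to first order, which
is far inside the statistical noise at these scales.

What the generator does *not* emulate: individual patient trajectories
and readmission dependence, geographic and provider structure, within-
year seasonality, migration shocks, coding drift, and the COVID era.
Passing tests therefore demonstrate that the estimator recovers known
components under clean NB sampling from a smooth world — not that the
exclusions, coding maps or model form are adequate for any particular
real extract.

## Problem sizes used by the test suite

The grid is always the full 9 years × 91 ages × 2 sexes (1,638 cells per
POD; 315 for maternity). Where absolute scale is irrelevant the tests
use a reduced `base_population` of ~3,000 persons per cell, and
event-level fixtures use ~20 per cell (event expansion is one row per
event; at the national-scale default it would materialise tens of
millions of rows, which is pointless for validating the filters).
Parameter-recovery runs use the national-scale default, where the NB
noise (dispersion 0.1) dominates scale anyway; the interval-coverage
experiment refits the ladder 200 times with the unpenalised engine, and
the Monte-Carlo oracle check uses 200,000 draws against the closed-form
lognormal-ratio quantiles.

## Known limitations

* The P/S/H intervals are structurally conservative (independence
  approximation; see above).
* The residual R is a black box: supply, policy, efficiency, unmet need
  and any mis-specification of the other rungs all land in it. A
  mitigation term is out of scope here.
* Health status enters as an average effect by age, sex and year; the
  CMS threshold (1.5) and the under-55 identity are modelling
  conventions, not estimates.
* Admission-method code lists are configurable defaults from the
  national data dictionary; real extracts must verify them.
* The Wald/GAM standard errors treat the smoothing parameter as fixed.
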