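# The generator: known-truth populations, life tables, prevalence and
# activity counts.

test_that("configuration validation names the offending field", {
  expect_error(generator_config(base_population = -1), "base_population")
  expect_error(generator_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(generator_config(baseline_year = 2019, end_year = 2011),
               "baseline_year")
  expect_error(generator_config(prevalence_params = list(p_max = 1.2)),
               "p_max")
})

test_that("population is stationary when growth and drift are zero", {
  cfg <- small_cfg(pop_growth_rate = 0, ageing_drift = 0)
  pop <- generate_population(cfg)
  base <- pop[pop$year == 2011, c("age", "sex", "count")]
  for (y in 2012:2019) {
    cur <- pop[pop$year == y, c("age", "sex", "count")]
    expect_equal(cur$count, base$count, tolerance = 1e-12)
  }
})

test_that("population totals form a geometric series at the growth rate", {
  cfg <- small_cfg(pop_growth_rate = 0.01, ageing_drift = 0)
  pop <- generate_population(cfg)
  tot <- tapply(pop$count, pop$year, sum)
  expect_equal(as.numeric(tot[-1] / tot[-length(tot)]), rep(1.01, 8),
               tolerance = 1e-9)
  expect_true(all(pop$count > 0))
})

test_that("default configuration ages: mean age rises monotonically", {
  pop <- generate_population(generator_config(seed = 1))
  mean_age <- vapply(split(pop, pop$year),
                     function(g) sum(g$age * g$count) / sum(g$count),
                     numeric(1))
  expect_true(all(diff(mean_age) > 0))
  # drift of 0.11 yr/yr should move the mean age by roughly that much
  expect_equal(unname(diff(range(mean_age))) / 8, 0.11, tolerance = 0.2)
})

test_that("life tables satisfy the survivorship axioms on every cell", {
  life <- generate_life_tables(small_cfg())
  expect_true(all(life$ex >= 0))
  for (g in split(life, list(life$year, life$sex), drop = TRUE)) {
    g <- g[order(g$age), ]
    expect_true(all(diff(g$lx) <= 0))
    expect_equal(g$lx[1], 1e5)
    # internal consistency: ex = sum of remaining Lx over lx
    expect_equal(g$ex, rev(cumsum(rev(g$Lx))) / g$lx, tolerance = 1e-6)
  }
})

test_that("zero mortality improvement freezes the life table across years", {
  life <- generate_life_tables(small_cfg(
    mortality_params = list(improvement = 0)))
  base <- life[life$year == 2011, c("age", "sex", "lx", "Lx", "ex")]
  for (y in 2012:2019) {
    expect_equal(life[life$year == y, c("age", "sex", "lx", "Lx", "ex")],
                 base, ignore_attr = TRUE)
  }
})

test_that("positive improvement makes e65 non-decreasing in calendar year", {
  life <- generate_life_tables(small_cfg())
  for (s in c("f", "m")) {
    e65 <- life$ex[life$age == 65 & life$sex == s]
    expect_true(all(diff(e65) >= 0))
  }
})

test_that("toy Gompertz life expectancy matches a quadrature oracle", {
  cfg <- small_cfg(mortality_params = list(level = 1e-4, slope = 0.1,
                                           male_mult = 1, improvement = 0))
  life <- generate_life_tables(cfg)
  # oracle: e0 = integral of S(a) = exp(-(level/slope) (exp(slope a) - 1))
  surv <- function(a) exp(-(1e-4 / 0.1) * (exp(0.1 * a) - 1))
  e0_oracle <- stats::integrate(surv, 0, 200, rel.tol = 1e-10)$value
  e0 <- life$ex[life$year == 2011 & life$age == 0 & life$sex == "f"]
  expect_equal(e0, e0_oracle, tolerance = 0.5 / e0_oracle)
})

test_that("noise-free prevalence is stationary without drift and monotone in age", {
  cfg <- small_cfg(prevalence_params = list(drift = 0))
  prev <- generate_prevalence(cfg, noise = FALSE)
  expect_equal(prev$p, prev$p_true)
  base <- prev[prev$year == 2011, "p"]
  for (y in 2012:2019) expect_equal(prev[prev$year == y, "p"], base)
  for (g in split(prev, list(prev$year, prev$sex), drop = TRUE)) {
    expect_true(all(diff(g$p[order(g$age)]) >= 0))
  }
})

test_that("binomial sampling noise in the prevalence table is unbiased", {
  cfg <- generator_config(seed = 1)  # 20,000 records per year
  prev <- generate_prevalence(cfg)
  err <- prev$p - prev$p_true
  # mean error over all cells vs the aggregate binomial standard error
  se <- sqrt(sum(prev$p_true * (1 - prev$p_true) / prev$n_sampled)) /
    nrow(prev)
  expect_lt(abs(mean(err)), 3 * se)
  expect_true(all(prev$p >= 0 & prev$p <= 1))
})

test_that("expected activity is stationary when all rates are frozen", {
  cfg <- small_cfg(pop_growth_rate = 0, ageing_drift = 0,
                   prevalence_params = list(drift = 0), residual_rate = 0)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "elective", noise = FALSE)
  base <- cnt[cnt$year == 2011, "mu"]
  for (y in 2012:2019) {
    expect_equal(cnt[cnt$year == y, "mu"], base, tolerance = 1e-12)
  }
})

test_that("maternity counts exist only for females aged 15-49", {
  cfg <- small_cfg()
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "maternity")
  expect_true(all(cnt$sex == "f"))
  expect_true(all(cnt$age >= 15 & cnt$age <= 49))
  expect_equal(nrow(cnt), 9 * 35)
  expect_error(generate_activity_counts(cfg, pop, "dialysis"), "pod")
})

test_that("the log of yearly activity totals grows at the residual rate", {
  cfg <- small_cfg(pop_growth_rate = 0, ageing_drift = 0,
                   prevalence_params = list(drift = 0), residual_rate = 0.02,
                   seed = 7)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "outpatient")
  tot <- tapply(cnt$count, cnt$year, sum)
  t <- as.numeric(names(tot)) - 2011
  fit <- stats::lm(log(tot) ~ t)
  slope <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(slope - log(1.02)), 3 * se)
})

test_that("generator output is deterministic given config and seed", {
  cfg <- small_cfg()
  pop <- generate_population(cfg)
  expect_identical(generate_population(cfg), pop)
  expect_identical(generate_prevalence(cfg), generate_prevalence(cfg))
  expect_identical(generate_activity_counts(cfg, pop, "ed"),
                   generate_activity_counts(cfg, pop, "ed"))
})

test_that("ground truth: zero drifts give zero components, P alone gives G = P", {
  cfg0 <- small_cfg(pop_growth_rate = 0, ageing_drift = 0,
                    prevalence_params = list(drift = 0), residual_rate = 0)
  gt0 <- ground_truth(cfg0)
  expect_equal(gt0$true_P, 0, tolerance = 1e-12)
  expect_equal(gt0$true_S, 0, tolerance = 1e-12)
  expect_equal(gt0$true_H, 0, tolerance = 1e-12)
  expect_equal(gt0$true_R, 0, tolerance = 1e-12)
  expect_equal(gt0$true_G, 0, tolerance = 1e-12)

  cfgP <- small_cfg(pop_growth_rate = 0.01, ageing_drift = 0,
                    prevalence_params = list(drift = 0), residual_rate = 0)
  gtP <- ground_truth(cfgP)
  expect_equal(gtP$true_P, 0.01, tolerance = 1e-9)
  expect_equal(gtP$true_G, 0.01, tolerance = 1e-9)
})

test_that("ground-truth product identity holds for arbitrary configurations", {
  set.seed(42)
  for (i in 1:5) {
    cfg <- small_cfg(pop_growth_rate = runif(1, -0.01, 0.02),
                     ageing_drift = runif(1, -0.1, 0.3),
                     prevalence_params = list(drift = runif(1, -0.05, 0.08)),
                     residual_rate = runif(1, -0.01, 0.04))
    gt <- ground_truth(cfg, pod = sample(c("elective", "ed", "maternity"), 1))
    expect_equal((1 + gt$true_P) * (1 + gt$true_S) * (1 + gt$true_H) *
                   (1 + gt$true_R) - 1,
                 gt$true_G, tolerance = 1e-12)
  }
})

test_that("ageing drift produces a positive S for an age-increasing rate curve", {
  cfg <- small_cfg(pop_growth_rate = 0, ageing_drift = 0.2,
                   prevalence_params = list(drift = 0), residual_rate = 0)
  gt <- ground_truth(cfg, pod = "elective")
  expect_gt(gt$true_S, 0)
  # and a healthier-drifting population drags H negative
  cfgH <- small_cfg(pop_growth_rate = 0, ageing_drift = 0,
                    prevalence_params = list(drift = 0.2), residual_rate = 0)
  expect_lt(ground_truth(cfgH, pod = "elective")$true_H, 0)
})

test_that("synthetic input files round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  write_synthetic_inputs(cfg, dir, pods = c("elective", "maternity"))
  pop <- read_population_table(file.path(dir, "population.csv"))
  expect_equal(pop, generate_population(cfg), tolerance = 1e-8)
  life <- read_life_table(file.path(dir, "lifetable.csv"))
  expect_equal(nrow(life), 9 * 91 * 2)
  prev <- read_prevalence_table(file.path(dir, "prevalence.csv"))
  expect_true(all(c("p", "n_sampled") %in% names(prev)))
  act <- read_activity_counts(file.path(dir, "activity.csv"))
  expect_setequal(unique(act$pod), c("elective", "maternity"))
})
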