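# The nested NB spline ladder and the year-coefficient estimand.

test_that("model specs encode the ladder structure", {
  expect_false(model_spec("M1", "elective")$include_offset)
  expect_equal(model_spec("M1", "elective")$smooth_covariate, "none")
  expect_true(model_spec("M2", "elective")$include_offset)
  expect_equal(model_spec("M3", "elective")$smooth_covariate, "age")
  expect_equal(model_spec("M4", "elective")$smooth_covariate, "hsa")
  expect_false(model_spec("M3", "maternity")$by_sex)
  expect_error(model_spec("M4", "maternity"), "undefined")
})

test_that("the M1 design has a centred year covariate and no offset", {
  tabs <- recovery_tables()
  cnt <- generate_activity_counts(tabs$cfg, tabs$pop, "elective")
  d <- build_design(cnt, spec = model_spec("M1", "elective"))
  expect_equal(sort(unique(d$year_c)), 0:8)
  expect_false("log_pop" %in% names(d))
  d2 <- build_design(cnt, tabs$pop, spec = model_spec("M2", "elective"))
  expect_true(all(d2$log_pop == log(d2$pop)))
})

test_that("misaligned grids are reported as an alignment error", {
  tabs <- recovery_tables()
  cnt <- generate_activity_counts(tabs$cfg, tabs$pop, "elective")
  pop_short <- tabs$pop[tabs$pop$age != 40, ]
  expect_error(build_design(cnt, pop_short, spec = model_spec("M2", "elective")),
               "does not cover")
})

test_that("zero-population cells are dropped with a message", {
  tabs <- recovery_tables()
  cnt <- generate_activity_counts(tabs$cfg, tabs$pop, "elective")
  pop0 <- tabs$pop
  pop0$count[pop0$age == 90 & pop0$sex == "m"] <- 0
  expect_message(
    d <- build_design(cnt, pop0, spec = model_spec("M2", "elective")),
    "zero population")
  expect_equal(nrow(d), nrow(cnt) - 9)
})

test_that("an exactly log-linear series is recovered to 1e-6 in the Poisson limit", {
  # counts doubling every year: beta_year = log(2) exactly
  d <- data.frame(pod = "elective", year = 2011:2016, age = 40, sex = "f",
                  count = 100 * 2^(0:5))
  des <- build_design(d, spec = model_spec("M1", "elective"))
  fit <- fit_nb_spline_model(des, fixed_theta = 1e8)
  expect_true(fit$converged)
  expect_equal(fit$beta_year, log(2), tolerance = 1e-6)
  expect_equal(annual_growth(fit), 1, tolerance = 1e-5)
})

test_that("a tiny M1 fit matches a brute-force NB likelihood grid search to 1e-4", {
  # 2 years x 2 ages, fixed dispersion so the oracle search is 2-dimensional
  d <- data.frame(pod = "ed", year = rep(2011:2012, each = 2),
                  age = rep(c(30, 60), 2), sex = "f",
                  count = c(52, 47, 61, 58))
  theta <- 5
  des <- build_design(d, spec = model_spec("M1", "ed"))
  fit <- fit_nb_spline_model(des, fixed_theta = theta)
  nll <- function(a, b) {
    -sum(stats::dnbinom(des$count, size = theta,
                        mu = exp(a + b * des$year_c), log = TRUE))
  }
  # coarse grid, then refine around the optimum
  a_grid <- seq(3, 5, length.out = 201)
  b_grid <- seq(-0.5, 0.5, length.out = 201)
  val <- outer(a_grid, b_grid, Vectorize(nll))
  ij <- arrayInd(which.min(val), dim(val))
  a_grid <- seq(a_grid[ij[1]] - 0.02, a_grid[ij[1]] + 0.02, length.out = 401)
  b_grid <- seq(b_grid[ij[2]] - 0.01, b_grid[ij[2]] + 0.01, length.out = 401)
  val <- outer(a_grid, b_grid, Vectorize(nll))
  ij <- arrayInd(which.min(val), dim(val))
  expect_equal(fit$beta_year, b_grid[ij[2]], tolerance = 1e-4)
})

test_that("M2 recovers a 2%/yr residual on NB data within 3 standard errors", {
  cfg <- small_cfg(pop_growth_rate = 0, ageing_drift = 0,
                   prevalence_params = list(drift = 0), residual_rate = 0.02,
                   seed = 19)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "non_elective")
  des <- build_design(cnt, pop, spec = model_spec("M2", "non_elective"))
  fit <- fit_nb_spline_model(des)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta_year - log(1.02)), 3 * fit$se_year)
  expect_gt(fit$dispersion, 0)
  expect_gt(fit$se_year, 0)
})

test_that("nesting sanity: M2 strips population growth that M1 reports", {
  cfg <- small_cfg(pop_growth_rate = 0.01, ageing_drift = 0,
                   prevalence_params = list(drift = 0), residual_rate = 0,
                   seed = 23)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "elective")
  f1 <- fit_nb_spline_model(build_design(cnt, spec = model_spec("M1", "elective")))
  f2 <- fit_nb_spline_model(build_design(cnt, pop, spec = model_spec("M2", "elective")))
  expect_lt(abs(f1$beta_year - log(1.01)), 3 * f1$se_year)
  expect_lt(abs(f2$beta_year), 3 * f2$se_year)
})

test_that("M4 reproduces M3 exactly when health-status age equals age", {
  cfg <- small_cfg(mortality_params = list(improvement = 0),
                   prevalence_params = list(drift = 0), seed = 29)
  pop <- generate_population(cfg)
  life <- generate_life_tables(cfg)
  prev <- generate_prevalence(cfg, noise = FALSE)
  hsa <- build_hsa_table(life, prev, 2011)
  expect_equal(hsa$hsa, as.numeric(hsa$age))
  cnt <- generate_activity_counts(cfg, pop, "outpatient")
  f3 <- fit_nb_spline_model(build_design(cnt, pop, spec = model_spec("M3", "outpatient")))
  f4 <- fit_nb_spline_model(build_design(cnt, pop, hsa, model_spec("M4", "outpatient")))
  expect_equal(f4$beta_year, f3$beta_year, tolerance = 1e-8)
  expect_equal(f4$se_year, f3$se_year, tolerance = 1e-8)
})

test_that("doubling every population cell and count leaves the offset models unchanged", {
  cfg <- small_cfg(seed = 31)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "ed")
  cnt2 <- cnt; cnt2$count <- 2L * cnt2$count
  pop2 <- pop; pop2$count <- 2 * pop2$count
  # the NB estimating equations are exactly scale-equivariant when the
  # variance scales with the data, i.e. with the size parameter doubled
  # alongside counts and offsets (the Poisson limit is the special case);
  # exactness requires an unpenalised basis -- a data-driven smoothing
  # penalty does not rescale with the likelihood
  for (id in c("M2", "M3")) {
    spec_a <- model_spec(id, "ed", method = "ns")
    fa <- fit_nb_spline_model(build_design(cnt, pop, spec = spec_a),
                              fixed_theta = 10)
    fb <- fit_nb_spline_model(build_design(cnt2, pop2, spec = spec_a),
                              fixed_theta = 20)
    expect_equal(fb$beta_year, fa$beta_year, tolerance = 1e-8)
  }
  # with the dispersion re-estimated from the doubled data the coefficient
  # moves only within numerical noise of the estimand
  fa <- fit_nb_spline_model(build_design(cnt, pop, spec = model_spec("M2", "ed")))
  fb <- fit_nb_spline_model(build_design(cnt2, pop2, spec = model_spec("M2", "ed")))
  expect_lt(abs(fb$beta_year - fa$beta_year), 1e-3)
})

test_that("the NB fit approaches the Poisson fit as dispersion vanishes", {
  cfg <- small_cfg(seed = 37)
  pop <- generate_population(cfg)
  cnt <- generate_activity_counts(cfg, pop, "elective")
  des <- build_design(cnt, pop, spec = model_spec("M2", "elective"))
  f_nb <- fit_nb_spline_model(des, fixed_theta = 1e8)
  f_pois <- mgcv::gam(count ~ year_c + offset(log_pop), family = stats::poisson(),
                      data = des, method = "REML")
  expect_equal(f_nb$beta_year, unname(coef(f_pois)["year_c"]),
               tolerance = 1e-6)
})

test_that("the unpenalised natural-spline path agrees with the penalised fit", {
  tabs <- recovery_tables()
  cnt <- generate_activity_counts(tabs$cfg, tabs$pop, "elective")
  f_gam <- fit_nb_spline_model(build_design(cnt, tabs$pop,
                                            spec = model_spec("M3", "elective")))
  f_ns <- fit_nb_spline_model(build_design(cnt, tabs$pop,
                                           spec = model_spec("M3", "elective",
                                                             method = "ns")))
  # the estimand is the year coefficient, which the basis barely moves
  expect_lt(abs(f_gam$beta_year - f_ns$beta_year), 2 * f_gam$se_year)
})

test_that("the year coefficient is insensitive to the basis dimension", {
  tabs <- recovery_tables()
  cnt <- generate_activity_counts(tabs$cfg, tabs$pop, "elective")
  betas <- vapply(c(8, 10, 14), function(k) {
    fit_nb_spline_model(build_design(cnt, tabs$pop,
                                     spec = model_spec("M3", "elective",
                                                       basis_df = k)))$beta_year
  }, numeric(1))
  expect_lt(diff(range(betas)), 0.2 * 0.01)
})

test_that("degenerate designs and non-converged fits are refused", {
  d <- data.frame(pod = "ed", year = 2011, age = c(30, 40), sex = "f",
                  count = c(1, 2))
  expect_error(fit_nb_spline_model(build_design(d, spec = model_spec("M1", "ed"))),
               "2 distinct years")
  d2 <- data.frame(pod = "ed", year = 2011:2012, age = 30, sex = "f", count = 0L)
  expect_error(fit_nb_spline_model(build_design(d2, spec = model_spec("M1", "ed"))),
               "all-zero")
  bad <- make_fit("M1", 0.01)
  bad$converged <- FALSE
  expect_error(annual_growth(bad), "converge")
})

test_that("annual growth is the exponentiated year coefficient minus one", {
  expect_equal(annual_growth(make_fit("M1", 0)), 0)
  expect_equal(annual_growth(make_fit("M1", log(1.0229))), 0.0229)
  expect_equal(annual_growth(make_fit("M1", -0.01)), exp(-0.01) - 1)
})
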