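# Synthetic-data generator: a parameterised generative model for the four
# analysis inputs (population, life tables, morbidity prevalence, activity
# counts) with known ground-truth growth components.
#
# The generative model is deliberately low-dimensional:
#   * population: a fixed smooth age density, shifted older by `ageing_drift`
#     years per calendar year, scaled to grow at `pop_growth_rate` per year;
#   * mortality: Gompertz hazards with a constant proportional improvement
#     per calendar year (male hazards a fixed multiple of female hazards);
#   * morbidity: a logistic-in-age prevalence curve, shifted older (i.e. the
#     population gets healthier) by `prevalence_drift` years per calendar
#     year, observed with binomial sampling noise;
#   * activity: negative-binomial counts around population x rate, where the
#     log rate holds an age-sex curve, a calendar trend (the residual), and,
#     at ages 55+, the same horizontal health-status displacement as the
#     prevalence curve.

# baseline age density of the synthetic population (ages in years);
# a working-age bulk plus a post-war cohort bump, calibrated so the lumped
# 90+ mean age at baseline is ~39.3 years
.age_density <- function(age) {
  stats::dnorm(age, 27, 23) + 0.27 * stats::dnorm(age, 63, 12)
}

# female share of the population by age (slight male excess at birth,
# female excess at old age)
.female_share <- function(age) {
  0.487 + 0.08 * stats::plogis((age - 70) / 12)
}

# extended single-year age grid used internally before 90+ lumping
.AGE_EXT <- 0:110

# baseline per-capita annual activity rates by point of delivery
# (maternity is per woman aged 15-49)
.POD_BASE_RATE <- c(
  elective = 0.167, non_elective = 0.108, maternity = 0.0956,
  outpatient = 1.185, ed = 0.248
)

# log-scale age shape of the activity rate curve for one pod; `age` may be
# fractional (the health-status displacement shifts it horizontally)
.pod_age_shape <- function(pod, age) {
  switch(pod,
    elective     = 1.8 * stats::plogis((age - 60) / 11) + 1.1 * exp(-age / 2),
    non_elective = 2.2 * stats::plogis((age - 68) / 11) + 1.6 * exp(-pmax(age, 0) / 1.5),
    outpatient   = 1.5 * stats::plogis((age - 55) / 14) + 0.7 * exp(-age / 3),
    ed           = 1.6 * stats::plogis((age - 72) / 10) + 1.2 * exp(-age / 6),
    maternity    = -((age - 29) / 6.5)^2 / 2,
    stopf("unknown pod '%s'", pod)
  )
}

# multiplicative sex effect on the activity rate (log scale)
.pod_sex_effect <- function(pod, sex) {
  eff <- switch(pod,
    elective = 0.05, non_elective = 0.05, outpatient = 0.15,
    ed = -0.05, maternity = 0
  )
  ifelse(sex == "f", eff, -eff)
}

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the generative model.  The
#' defaults emulate England 2011--2019 at national scale: a population of
#' ~53 million growing at 0.73% per year with mean age rising ~0.11 years
#' per year, Gompertz mortality improving 1% per year, and an age-logistic
#' morbidity prevalence (proportion with Cambridge Multimorbidity Score
#' > 1.5 of ~9.7% in females, ~7.3% in males) sampled at 20,000 records per
#' year.
#'
#' @param baseline_year,end_year inclusive calendar range of the study
#'   period (defaults 2011 and 2019).
#' @param base_population mean persons per (age, sex) cell at baseline; the
#'   baseline total is `182 * base_population`.
#' @param pop_growth_rate proportional growth of the total population per
#'   year (the true P component).
#' @param ageing_drift years by which the population age profile shifts
#'   older per calendar year (drives the true S component).
#' @param mortality_params list with elements `level` and `slope` (Gompertz
#'   hazard `level * exp(slope * age)` for females), `male_mult`
#'   (multiplier on male hazards) and `improvement` (proportional hazard
#'   decline per calendar year).
#' @param prevalence_params list with elements `p_max`, `age_mid`,
#'   `age_scale` (prevalence `p_max * plogis((age - age_mid)/age_scale)`),
#'   `sex_shift` (years subtracted from/added to `age_mid` for
#'   females/males) and `drift` (years by which the curve shifts older --
#'   i.e. the population gets healthier -- per calendar year; drives the
#'   true H component).
#' @param residual_rate proportional growth added to every activity rate
#'   per year (the true R component).
#' @param nb_dispersion negative-binomial overdispersion `phi` > 0, with
#'   `Var = mu + phi * mu^2` (the NB size parameter is `1/phi`).
#' @param prevalence_sample_n persons sampled per year for the observed
#'   prevalence table.
#' @param seed integer seed from which all generator draws derive.
#' @return a validated list of class `"generator_config"`.
#' @examples
#' cfg <- generator_config(base_population = 2000, seed = 42)
#' pop <- generate_population(cfg)
#' head(pop)
#' @export
generator_config <- function(baseline_year = 2011, end_year = 2019,
                             base_population = 292000,
                             pop_growth_rate = 0.0073,
                             ageing_drift = 0.11,
                             mortality_params = list(),
                             prevalence_params = list(),
                             residual_rate = 0.01,
                             nb_dispersion = 0.1,
                             prevalence_sample_n = 20000,
                             seed = 1L) {
  mort <- utils::modifyList(
    list(level = 2.2e-5, slope = 0.095, male_mult = 1.45, improvement = 0.01),
    mortality_params
  )
  prev <- utils::modifyList(
    list(p_max = 0.72, age_mid = 76, age_scale = 12, sex_shift = 2, drift = 0.02),
    prevalence_params
  )
  cfg <- list(
    baseline_year = as.integer(baseline_year), end_year = as.integer(end_year),
    ages = 0:90,
    base_population = base_population, pop_growth_rate = pop_growth_rate,
    ageing_drift = ageing_drift, mortality_params = mort,
    prevalence_params = prev, residual_rate = residual_rate,
    nb_dispersion = nb_dispersion, prevalence_sample_n = prevalence_sample_n,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!inherits(cfg, "generator_config")) stopf("not a generator_config")
  if (!is.finite(cfg$base_population) || cfg$base_population <= 0) {
    stopf("invalid generator configuration: `base_population` must be > 0")
  }
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stopf("invalid generator configuration: `nb_dispersion` must be > 0")
  }
  if (cfg$baseline_year >= cfg$end_year) {
    stopf("invalid generator configuration: `baseline_year` must precede `end_year`")
  }
  if (!identical(cfg$ages, 0:90)) {
    stopf("invalid generator configuration: `ages` must cover 0..90 with no gaps")
  }
  pm <- cfg$prevalence_params
  if (pm$p_max < 0 || pm$p_max > 1) {
    stopf("invalid generator configuration: `prevalence_params$p_max` must lie in [0,1]")
  }
  if (cfg$prevalence_sample_n <= 0) {
    stopf("invalid generator configuration: `prevalence_sample_n` must be > 0")
  }
  if (cfg$mortality_params$level <= 0 || cfg$mortality_params$slope <= 0) {
    stopf("invalid generator configuration: `mortality_params` level/slope must be > 0")
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-data generator configuration\n")
  cat(sprintf("  years:            %d..%d (baseline %d)\n",
              x$baseline_year, x$end_year, x$baseline_year))
  cat(sprintf("  base population:  %s per age-sex cell (total %.1fM)\n",
              format(x$base_population, big.mark = ","),
              182 * x$base_population / 1e6))
  cat(sprintf("  true P (pop growth):     %+.4f / yr\n", x$pop_growth_rate))
  cat(sprintf("  ageing drift:            %+.3f yr / yr\n", x$ageing_drift))
  cat(sprintf("  prevalence drift:        %+.3f yr / yr\n",
              x$prevalence_params$drift))
  cat(sprintf("  true R (residual rate):  %+.4f / yr\n", x$residual_rate))
  cat(sprintf("  NB dispersion:           %.3f\n", x$nb_dispersion))
  invisible(x)
}

# internal: population weights over the extended age grid for year index t
# (t = year - baseline_year), before 90+ lumping; normalised to sum to 1
.pop_weights_ext <- function(cfg, t) {
  dens <- .age_density(.AGE_EXT - cfg$ageing_drift * t)
  shf <- .female_share(.AGE_EXT)
  w <- c(dens * shf, dens * (1 - shf))  # f block then m block
  w / sum(w)
}

# internal: population counts on the lumped 0..90 grid for year index t,
# as a data.frame(age, sex, count)
.population_year <- function(cfg, t) {
  w <- .pop_weights_ext(cfg, t)
  total <- cfg$base_population * 182 * (1 + cfg$pop_growth_rate)^t
  n_ext <- length(.AGE_EXT)
  lump <- pmin(.AGE_EXT, 90)
  cf <- vapply(split(w[seq_len(n_ext)] * total, lump), sum, numeric(1))
  cm <- vapply(split(w[n_ext + seq_len(n_ext)] * total, lump), sum, numeric(1))
  data.frame(
    age = rep(0:90, 2L),
    sex = rep(c("f", "m"), each = 91L),
    count = c(cf, cm),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic mid-year population table
#'
#' Deterministic given the configuration: the total population grows
#' geometrically at `pop_growth_rate` per year and the age profile shifts
#' older by `ageing_drift` years per year.  Ages above 90 are lumped into
#' the open 90+ group, coded as age 90.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `year`, `age` (0..90, 90 = "90+"),
#'   `sex` ("f"/"m") and `count` (> 0).
#' @export
generate_population <- function(config) {
  config <- validate_generator_config(config)
  years <- config$baseline_year:config$end_year
  out <- do.call(rbind, lapply(seq_along(years), function(i) {
    df <- .population_year(config, i - 1L)
    cbind(year = years[i], df)
  }))
  rownames(out) <- NULL
  out
}

# internal: full life table on the extended age grid for one (year, sex)
.life_table_ext <- function(cfg, t, sex) {
  mp <- cfg$mortality_params
  mult <- if (sex == "m") mp$male_mult else 1
  haz <- mp$level * mult * exp(mp$slope * (.AGE_EXT + 0.5)) *
    (1 - mp$improvement)^t
  radix <- 1e5
  lx <- radix * c(1, exp(-cumsum(haz)))[seq_along(.AGE_EXT)]
  if (any(!is.finite(lx))) stopf("life-table generation produced non-finite survivorship")
  dx <- c(-diff(lx), lx[length(lx)])
  Lx <- lx - 0.5 * dx
  # close out the table at the top of the extended grid
  Lx[length(Lx)] <- lx[length(lx)] / haz[length(haz)]
  Tx <- rev(cumsum(rev(Lx)))
  list(age = .AGE_EXT, lx = lx, Lx = Lx, Tx = Tx, ex = Tx / lx)
}

#' Generate synthetic period life tables
#'
#' Gompertz mortality (`level * exp(slope * age)`, male hazards scaled by
#' `male_mult`) with a constant proportional improvement per calendar year.
#' The table is tabulated on ages 0..90 with an open 90+ interval whose
#' person-years column absorbs the whole tail, so that
#' `ex = sum(Lx[age >= x]) / lx` holds exactly on the tabulated grid.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `year`, `age` (0..90), `sex`, `lx`
#'   (survivors at exact age, radix 100,000), `Lx` (person-years lived in
#'   the interval; open-ended at 90) and `ex` (remaining period life
#'   expectancy, years).
#' @export
generate_life_tables <- function(config) {
  config <- validate_generator_config(config)
  years <- config$baseline_year:config$end_year
  grid <- expand.grid(year = years, sex = c("f", "m"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    t <- grid$year[i] - config$baseline_year
    lt <- .life_table_ext(config, t, grid$sex[i])
    keep <- lt$age <= 90
    lx <- lt$lx[keep]
    Lx <- lt$Lx[keep]
    Lx[91] <- lt$Tx[91]  # open 90+ interval: all remaining person-years
    ex <- rev(cumsum(rev(Lx))) / lx
    data.frame(year = grid$year[i], age = 0:90, sex = grid$sex[i],
               lx = lx, Lx = Lx, ex = ex, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$year, out$sex, out$age), ]
  rownames(out) <- NULL
  out
}

# internal: true prevalence curve at integer ages for year index t
.prevalence_true <- function(cfg, t, age, sex) {
  pm <- cfg$prevalence_params
  mid <- ifelse(sex == "f", pm$age_mid - pm$sex_shift, pm$age_mid + pm$sex_shift)
  pm$p_max * stats::plogis((age - pm$drift * t - mid) / pm$age_scale)
}

#' Generate a synthetic morbidity-prevalence table
#'
#' The true prevalence of major illness (CMS > 1.5) follows a logistic
#' curve in age, shifted older by `drift` years per calendar year (a
#' positive drift means the population is getting healthier).  Observed
#' prevalence adds binomial sampling noise from an annual sample of
#' `prevalence_sample_n` persons allocated to (age, sex) cells proportional
#' to population.
#'
#' @param config a [generator_config()].
#' @param noise if `FALSE`, the observed prevalence equals the true curve
#'   (the infinite-sample limit) and `n_sampled` is reported as `NA`.
#' @return data.frame with columns `year`, `age`, `sex`, `n_sampled`,
#'   `p` (observed proportion with CMS > 1.5) and `p_true`.
#' @export
generate_prevalence <- function(config, noise = TRUE) {
  config <- validate_generator_config(config)
  years <- config$baseline_year:config$end_year
  pop <- generate_population(config)
  out <- do.call(rbind, lapply(years, function(y) {
    t <- y - config$baseline_year
    py <- pop[pop$year == y, ]
    p_true <- .prevalence_true(config, t, py$age, py$sex)
    if (noise) {
      n_cell <- pmax(1L, round(config$prevalence_sample_n * py$count / sum(py$count)))
      x <- with_seed(config$seed + 1000L + t, stats::rbinom(length(n_cell), n_cell, p_true))
      p_obs <- x / n_cell
    } else {
      n_cell <- NA_integer_
      p_obs <- p_true
    }
    data.frame(year = y, age = py$age, sex = py$sex, n_sampled = n_cell,
               p = p_obs, p_true = p_true, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# internal: effective age after the health-status displacement; the
# displacement applies from age 55 up, mirroring the health-status-age
# construct (under-55 health status is held fixed)
.effective_age <- function(age, drift, t) {
  ifelse(age >= 55, age - drift * t, age)
}

# internal: deterministic mean activity rate per person for pod at year
# index t (excluding the residual calendar trend if `residual = FALSE`)
.activity_rate <- function(cfg, pod, age, sex, t, residual = TRUE,
                           health_shift = TRUE) {
  a_eff <- if (health_shift) {
    .effective_age(age, cfg$prevalence_params$drift, t)
  } else {
    age
  }
  shape <- .pod_age_shape(pod, a_eff) + .pod_sex_effect(pod, sex)
  rate <- exp(shape)
  # normalise so the baseline population-weighted mean rate equals the
  # pod's headline per-capita rate
  base <- .population_year(cfg, 0)
  if (pod == "maternity") base <- base[base$sex == "f" & base$age %in% MATERNITY_AGES, ]
  shape0 <- .pod_age_shape(pod, base$age) + .pod_sex_effect(pod, base$sex)
  norm <- sum(base$count * exp(shape0)) / sum(base$count)
  out <- .POD_BASE_RATE[[pod]] * rate / norm
  if (residual) out <- out * (1 + cfg$residual_rate)^t
  out
}

#' Generate synthetic activity counts for one point of delivery
#'
#' Counts are negative-binomial around `population x rate`, where the log
#' rate carries the pod's age-sex curve, the residual calendar trend
#' (`residual_rate` per year) and, at ages 55+, a horizontal age
#' displacement equal to the prevalence drift (healthier cohorts behave
#' like younger ones).  The maternity pod is restricted to females aged
#' 15--49.
#'
#' @param config a [generator_config()].
#' @param population table from [generate_population()].
#' @param pod one of `"elective"`, `"non_elective"`, `"maternity"`,
#'   `"outpatient"`, `"ed"`.
#' @param noise if `FALSE`, returns the expected counts (`count == mu`).
#' @return data.frame with columns `pod`, `year`, `age`, `sex`, `count`
#'   and `mu` (the expected count; dropped when written to file).
#' @export
generate_activity_counts <- function(config, population, pod, noise = TRUE) {
  config <- validate_generator_config(config)
  check_pod(pod)
  check_columns(population, c("year", "age", "sex", "count"), "population")
  dat <- population
  if (pod == "maternity") {
    dat <- dat[dat$sex == "f" & dat$age %in% MATERNITY_AGES, ]
  }
  t <- dat$year - config$baseline_year
  mu <- dat$count * .activity_rate(config, pod, dat$age, dat$sex, t)
  count <- if (noise) {
    pod_off <- 13L * match(pod, POD_LEVELS)
    with_seed(config$seed + 2000L + pod_off,
              stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu))
  } else {
    mu
  }
  out <- data.frame(pod = pod, year = dat$year, age = dat$age, sex = dat$sex,
                    count = count, mu = mu, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ground-truth growth components of a synthetic configuration
#'
#' Computes the generator's true P, S, H and R for one point of delivery.
#' P and R are exact by construction (`pop_growth_rate` and
#' `residual_rate`).  S and H depend on the pod's age-rate curve, so they
#' are computed from the generator's deterministic mean surfaces: S as the
#' annualised log-linear growth of the baseline-rate-standardised activity
#' under the shifting age profile, H as the annualised growth of activity
#' under the health-status displacement at fixed baseline population.
#' `true_G` follows from the product identity
#' `(1+P)(1+S)(1+H)(1+R) - 1`.
#'
#' @param config a [generator_config()].
#' @param pod point of delivery whose rate curve standardises S and H
#'   (default `"elective"`).
#' @return list of class `"ground_truth"` with elements `true_P`,
#'   `true_S`, `true_H`, `true_R`, `true_G`.
#' @export
ground_truth <- function(config, pod = "elective") {
  config <- validate_generator_config(config)
  check_pod(pod)
  years <- config$baseline_year:config$end_year
  tt <- years - config$baseline_year

  base <- .population_year(config, 0)
  sub <- function(df) {
    if (pod == "maternity") df[df$sex == "f" & df$age %in% MATERNITY_AGES, ] else df
  }
  base_s <- sub(base)
  rate0 <- .activity_rate(config, pod, base_s$age, base_s$sex, 0,
                          residual = FALSE, health_shift = FALSE)

  pop_tot <- numeric(length(tt))
  s_fact <- numeric(length(tt))
  h_fact <- numeric(length(tt))
  for (i in seq_along(tt)) {
    py <- sub(.population_year(config, tt[i]))
    pop_tot[i] <- sum(py$count)
    # S: shifting weights, frozen baseline rates
    s_fact[i] <- sum(py$count * rate0) / sum(py$count)
    # H: frozen baseline weights, displaced rates (no residual trend)
    r_t <- .activity_rate(config, pod, base_s$age, base_s$sex, tt[i],
                          residual = FALSE, health_shift = TRUE)
    h_fact[i] <- sum(base_s$count * r_t) / sum(base_s$count * rate0)
  }
  logslope <- function(v) unname(stats::coef(stats::lm(log(v) ~ tt))[2L])
  true_P <- exp(logslope(pop_tot)) - 1
  true_S <- exp(logslope(s_fact)) - 1
  true_H <- if (config$prevalence_params$drift == 0) 0 else exp(logslope(h_fact)) - 1
  true_R <- config$residual_rate
  out <- list(true_P = true_P, true_S = true_S, true_H = true_H,
              true_R = true_R,
              true_G = compute_total_growth(true_P, true_S, true_H, true_R),
              pod = pod)
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth (%s): G=%s P=%s S=%s H=%s R=%s\n", x$pod,
              fmt_pct(x$true_G), fmt_pct(x$true_P), fmt_pct(x$true_S),
              fmt_pct(x$true_H), fmt_pct(x$true_R)))
  invisible(x)
}

# default admission-method code lists (NHS data dictionary conventions)
ADMISSION_METHOD_CODES <- list(
  elective = c("11", "12", "13"),
  non_elective = c("21", "22", "23", "24", "25", "2A", "2B", "2C", "2D", "28"),
  maternity = c("31", "32")
)

#' Expand activity counts into synthetic event-level records
#'
#' Produces one row per event with the record-level fields the ingest
#' filters act on, optionally injecting a known number of records that
#' those filters must remove.  Injected records are appended to the clean
#' expansion, so with zero contamination the aggregation of the output
#' reproduces the input counts exactly.
#'
#' @param counts table from [generate_activity_counts()] (any subset of
#'   pods).
#' @param contamination named list of proportions (of the clean record
#'   count) to inject per exclusion rule; recognised names:
#'   `non_england`, `invalid_age`, `invalid_sex`, `opa_status` (outpatient
#'   attendance-status codes 2/3/4/7), `ed_type` (non-type-1 ED).
#' @param seed integer seed for the expansion draws.
#' @return data.frame of event records with attribute `"injected"`, a
#'   named integer vector of per-rule injected counts.
#' @export
generate_event_records <- function(counts, contamination = list(), seed = 1L) {
  check_columns(counts, c("pod", "year", "age", "sex", "count"), "counts")
  rules <- c("non_england", "invalid_age", "invalid_sex", "opa_status", "ed_type")
  contam <- utils::modifyList(
    stats::setNames(as.list(rep(0, length(rules))), rules),
    contamination
  )
  cvals <- unlist(contam[rules])
  if (any(cvals < 0 | cvals > 1)) {
    stopf("contamination proportions must lie in [0, 1]")
  }
  counts <- counts[counts$count > 0, , drop = FALSE]
  n_clean <- sum(counts$count)

  with_seed(seed, {
    idx <- rep(seq_len(nrow(counts)), counts$count)
    rec <- data.frame(
      pod_raw = ifelse(counts$pod[idx] %in% c("elective", "non_elective", "maternity"),
                       "inpatient", counts$pod[idx]),
      admission_method = NA_character_,
      attendance_status = NA_character_,
      department_type = NA_character_,
      treatment_function = sample(c("100", "110", "301", "424"), length(idx),
                                  replace = TRUE, prob = c(0.5, 0.25, 0.2, 0.05)),
      age = counts$age[idx],
      sex = counts$sex[idx],
      resident_in_england = TRUE,
      year = counts$year[idx],
      stringsAsFactors = FALSE
    )
    for (p in c("elective", "non_elective", "maternity")) {
      sel <- counts$pod[idx] == p
      if (any(sel)) {
        rec$admission_method[sel] <- sample(ADMISSION_METHOD_CODES[[p]],
                                            sum(sel), replace = TRUE)
      }
    }
    sel <- rec$pod_raw == "outpatient"
    rec$attendance_status[sel] <- sample(c("5", "6"), sum(sel), replace = TRUE)
    rec$department_type[rec$pod_raw == "ed"] <- "1"

    # injected bad records, each violating exactly one rule
    n_inj <- stats::setNames(as.integer(round(cvals * n_clean)), rules)
    bad <- list()
    mk_base <- function(n) {
      i <- sample(nrow(rec), n, replace = TRUE)
      rec[i, , drop = FALSE]
    }
    if (n_inj[["non_england"]] > 0) {
      b <- mk_base(n_inj[["non_england"]])
      b$resident_in_england <- FALSE
      bad <- c(bad, list(b))
    }
    if (n_inj[["invalid_age"]] > 0) {
      b <- mk_base(n_inj[["invalid_age"]])
      b$age <- sample(c(NA_integer_, 999L, -1L), nrow(b), replace = TRUE)
      bad <- c(bad, list(b))
    }
    if (n_inj[["invalid_sex"]] > 0) {
      b <- mk_base(n_inj[["invalid_sex"]])
      b$sex <- sample(c(NA_character_, "u"), nrow(b), replace = TRUE)
      bad <- c(bad, list(b))
    }
    if (n_inj[["opa_status"]] > 0) {
      b <- mk_base(n_inj[["opa_status"]])
      b$pod_raw <- "outpatient"
      b$admission_method <- NA_character_
      b$department_type <- NA_character_
      b$attendance_status <- sample(c("2", "3", "4", "7"), nrow(b), replace = TRUE)
      bad <- c(bad, list(b))
    }
    if (n_inj[["ed_type"]] > 0) {
      b <- mk_base(n_inj[["ed_type"]])
      b$pod_raw <- "ed"
      b$admission_method <- NA_character_
      b$attendance_status <- NA_character_
      b$department_type <- "2"
      bad <- c(bad, list(b))
    }
    out <- do.call(rbind, c(list(rec), bad))
    rownames(out) <- NULL
    attr(out, "injected") <- n_inj
    out
  })
}

#' Write the four synthetic input tables as CSV files
#'
#' Emits `population.csv` (year,age,sex,count), `lifetable.csv`
#' (year,age,sex,lx,Lx,ex), `prevalence.csv`
#' (year,age,sex,n_sampled,p_cms_gt_1_5) and `activity.csv`
#' (pod,year,age,sex,count), UTF-8 comma-delimited with header rows.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @param pods pods to include in `activity.csv`.
#' @return invisibly, the vector of file paths written.
#' @export
write_synthetic_inputs <- function(config, dir, pods = POD_LEVELS) {
  config <- validate_generator_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(config)
  life <- generate_life_tables(config)
  prev <- generate_prevalence(config)
  act <- do.call(rbind, lapply(pods, function(p) {
    generate_activity_counts(config, pop, p)[, c("pod", "year", "age", "sex", "count")]
  }))
  paths <- file.path(dir, c("population.csv", "lifetable.csv",
                            "prevalence.csv", "activity.csv"))
  utils::write.csv(pop, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(life[, c("year", "age", "sex", "lx", "Lx", "ex")],
                   paths[2], row.names = FALSE, quote = FALSE)
  prev_out <- prev[, c("year", "age", "sex", "n_sampled", "p")]
  names(prev_out)[5] <- "p_cms_gt_1_5"
  utils::write.csv(prev_out, paths[3], row.names = FALSE, quote = FALSE)
  utils::write.csv(act, paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read the delimited input tables
#'
#' Readers for the CSV dialects written by [write_synthetic_inputs()]:
#' population (year,age,sex,count), life table (year,age,sex,lx,Lx,ex),
#' prevalence (year,age,sex,n_sampled,p_cms_gt_1_5 -- returned with the
#' proportion renamed to `p`) and activity counts (pod,year,age,sex,count).
#'
#' @param path file path.
#' @return data.frame in the package's canonical column layout.
#' @name input_readers
NULL

#' @rdname input_readers
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "age", "sex", "count"), basename(path))
  df
}

#' @rdname input_readers
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "age", "sex", "lx", "Lx", "ex"), basename(path))
  df
}

#' @rdname input_readers
#' @export
read_prevalence_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "age", "sex", "n_sampled", "p_cms_gt_1_5"),
                basename(path))
  names(df)[names(df) == "p_cms_gt_1_5"] <- "p"
  df
}

#' @rdname input_readers
#' @export
read_activity_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("pod", "year", "age", "sex", "count"), basename(path))
  df
}
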