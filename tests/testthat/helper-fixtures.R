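# Shared fixtures, built in code at test time.

# small synthetic configuration used where the absolute scale is irrelevant
small_cfg <- function(...) {
  args <- utils::modifyList(list(base_population = 3000, seed = 101),
                            list(...))
  do.call(generator_config, args)
}

# the known-truth recovery configuration: P = 1%/yr, S = H = 0,
# R = 2%/yr, NB dispersion 0.1, at the default population scale
recovery_cfg <- function(seed = 11) {
  generator_config(pop_growth_rate = 0.01, ageing_drift = 0,
                   prevalence_params = list(drift = 0),
                   residual_rate = 0.02, nb_dispersion = 0.1, seed = seed)
}

# cache deterministic tables that several test files reuse
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

recovery_tables <- function() {
  cached("recovery_tables", {
    cfg <- recovery_cfg()
    pop <- generate_population(cfg)
    life <- generate_life_tables(cfg)
    prev <- generate_prevalence(cfg)
    list(cfg = cfg, pop = pop, life = life, prev = prev,
         hsa = build_hsa_table(life, prev, cfg$baseline_year))
  })
}

# a fake converged model fit with a given year coefficient, for exercising
# the decomposition algebra without a regression
make_fit <- function(model_id, beta, se = 0.005, pod = "elective") {
  structure(list(model_id = model_id, pod = pod, beta_year = beta,
                 se_year = se, dispersion = 0.1, theta = 10,
                 log_likelihood = NA_real_, converged = TRUE,
                 n_cells = NA_integer_, method = "fake"),
            class = "nb_growth_fit")
}

make_ladder <- function(b1, b2, b3, b4 = NULL, se = 0.005,
                        pod = if (is.null(b4)) "maternity" else "elective") {
  betas <- c(M1 = b1, M2 = b2, M3 = b3)
  if (!is.null(b4)) betas["M4"] <- b4
  lapply_names <- names(betas)
  stats::setNames(lapply(lapply_names, function(id) {
    make_fit(id, betas[[id]], se = se, pod = pod)
  }), lapply_names)
}

# Table-2 component rows (percent): the published decomposition estimates
published_components <- function() {
  data.frame(
    pod = c("elective", "non_elective", "maternity", "outpatient", "ed"),
    P = c(0.88, 0.59, 0.41, 0.61, 0.27),
    S = c(0.69, 0.25, -0.08, 0.46, 0.09),
    H = c(-0.03, 0.18, 0.00, -0.02, 0.09),
    R = c(0.73, 1.65, -1.02, 3.41, 0.84),
    G = c(2.29, 2.69, -0.70, 4.51, 1.29)
  )
}
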