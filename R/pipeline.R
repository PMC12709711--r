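# End-to-end orchestration: (generate | load) -> health-status age ->
# model ladder per pod -> decomposition -> report files.

#' Pipeline configuration
#'
#' @param input_mode `"synthetic"` (generate everything from `generator`)
#'   or `"files"` (read the four delimited tables from `paths`).
#' @param generator a [generator_config()] (synthetic mode).
#' @param paths named list with elements `population`, `lifetable`,
#'   `prevalence`, `activity` (files mode).
#' @param pods non-empty subset of the five points of delivery.
#' @param baseline_year baseline for the health-status-age transform and
#'   year centring; defaults to the earliest year in the data.
#' @param basis_df,method model-ladder settings (see [model_spec()]).
#' @param n_sims,level Monte-Carlo interval settings.
#' @param seed master seed for all stochastic steps.
#' @param output_dir if non-`NULL`, results, report and manifest files are
#'   written there.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "files"),
                            generator = generator_config(),
                            paths = NULL, pods = POD_LEVELS,
                            baseline_year = NULL, basis_df = 10,
                            method = c("reml", "ns"), n_sims = 1000,
                            level = 0.95, seed = 1L, output_dir = NULL) {
  input_mode <- match.arg(input_mode)
  method <- match.arg(method)
  if (length(pods) == 0L || !all(pods %in% POD_LEVELS)) {
    stopf("`pods` must be a non-empty subset of: %s",
          paste(POD_LEVELS, collapse = ", "))
  }
  if (input_mode == "files") {
    need <- c("population", "lifetable", "prevalence", "activity")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stopf("files mode needs `paths` with elements: %s",
            paste(need, collapse = ", "))
    }
  }
  out <- list(input_mode = input_mode, generator = generator, paths = paths,
              pods = pods, baseline_year = baseline_year,
              basis_df = basis_df, method = method, n_sims = n_sims,
              level = level, seed = as.integer(seed),
              output_dir = output_dir)
  class(out) <- "pipeline_config"
  out
}

#' Validate the four input tables
#'
#' Checks schemas, value ranges (counts >= 0, prevalence in [0, 1],
#' survivorship non-increasing in age), grid completeness and year
#' coverage.  Problems are reported with the table, cell and rule that
#' failed.
#'
#' @param tables named list with elements `population`, `lifetable`,
#'   `prevalence`, `activity` -- data.frames in the canonical layouts (see
#'   [input_readers]).
#' @param stop_on_error signal an error on the first report (default);
#'   otherwise return the full report.
#' @return character vector of problem messages (empty when the inputs
#'   are well-formed), invisibly when `stop_on_error = TRUE`.
#' @export
validate_inputs <- function(tables, stop_on_error = TRUE) {
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  pop <- tables$population
  check_columns(pop, c("year", "age", "sex", "count"), "population")
  if (any(pop$count < 0)) {
    i <- which(pop$count < 0)[1]
    note("population: negative count at year=%s age=%s sex=%s",
         pop$year[i], pop$age[i], pop$sex[i])
  }
  years <- sort(unique(pop$year))
  grid_n <- length(years) * 91L * 2L
  if (nrow(unique(pop[, c("year", "age", "sex")])) != grid_n) {
    note("population: grid incomplete (expected %d cells, found %d)",
         grid_n, nrow(unique(pop[, c("year", "age", "sex")])))
  }

  life <- tables$lifetable
  check_columns(life, c("year", "age", "sex", "lx", "Lx", "ex"), "lifetable")
  for (g in split(life, list(life$year, life$sex), drop = TRUE)) {
    g <- g[order(g$age), ]
    if (any(diff(g$lx) > 1e-9)) {
      note("lifetable: lx increasing in age for year=%s sex=%s",
           g$year[1], g$sex[1])
    }
    if (any(g$ex < 0)) {
      note("lifetable: negative life expectancy for year=%s sex=%s",
           g$year[1], g$sex[1])
    }
  }
  if (!all(years %in% unique(life$year))) {
    note("lifetable: year coverage does not span the population years")
  }

  prev <- tables$prevalence
  check_columns(prev, c("year", "age", "sex", "p"), "prevalence")
  bad <- which(prev$p < 0 | prev$p > 1)
  if (length(bad)) {
    i <- bad[1]
    note("prevalence: p=%s outside [0,1] at year=%s age=%s sex=%s",
         format(prev$p[i]), prev$year[i], prev$age[i], prev$sex[i])
  }

  act <- tables$activity
  check_columns(act, c("pod", "year", "age", "sex", "count"), "activity")
  if (any(act$count < 0)) {
    i <- which(act$count < 0)[1]
    note("activity: negative count at pod=%s year=%s age=%s sex=%s",
         act$pod[i], act$year[i], act$age[i], act$sex[i])
  }
  if (!all(act$pod %in% POD_LEVELS)) {
    note("activity: unknown pod label(s): %s",
         paste(setdiff(unique(act$pod), POD_LEVELS), collapse = ", "))
  }

  if (stop_on_error && length(problems)) {
    stopf("input validation failed:\n  %s", paste(problems, collapse = "\n  "))
  }
  if (stop_on_error) invisible(problems) else problems
}

#' Run the full decomposition pipeline
#'
#' Generates (or loads) the four input tables, builds the
#' health-status-age covariate, fits the model ladder for each requested
#' point of delivery, decomposes growth, and optionally writes
#' `results.csv` (long format), `report.md` (publication-table shape) and
#' `manifest.json` (seed, configuration fingerprint, versions, per-model
#' convergence and output file hashes).  A pod whose fit fails is
#' recorded in `errors` without aborting the rest; if no pod succeeds the
#' run errors.
#'
#' @param config a [pipeline_config()].
#' @return list with `decompositions` (named list of [pod_growth()]
#'   objects), `results` (long data.frame), `table` (formatted report
#'   table), `errors` (named character), `inputs` (the tables used) and
#'   `files` (paths written, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$input_mode == "synthetic") {
    gen <- config$generator
    gen$seed <- config$seed
    pop <- generate_population(gen)
    life <- generate_life_tables(gen)
    prev <- generate_prevalence(gen)
    act <- do.call(rbind, lapply(config$pods, function(p) {
      generate_activity_counts(gen, pop, p)[, c("pod", "year", "age", "sex", "count")]
    }))
  } else {
    pop <- read_population_table(config$paths$population)
    life <- read_life_table(config$paths$lifetable)
    prev <- read_prevalence_table(config$paths$prevalence)
    act <- read_activity_counts(config$paths$activity)
    validate_inputs(list(population = pop, lifetable = life,
                         prevalence = prev, activity = act))
  }
  baseline <- if (is.null(config$baseline_year)) min(pop$year) else config$baseline_year
  hsa <- build_hsa_table(life, prev, baseline)

  decs <- list()
  errors <- character()
  for (i in seq_along(config$pods)) {
    p <- config$pods[i]
    res <- tryCatch(
      pod_growth(act[act$pod == p, , drop = FALSE], pop, hsa, pod = p,
                 basis_df = config$basis_df, year_reference = baseline,
                 method = config$method, n_sims = config$n_sims,
                 seed = config$seed + 17L * i, level = config$level),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[p] <- conditionMessage(res)
    } else {
      decs[[p]] <- res
    }
  }
  if (length(decs) == 0L) {
    stopf("no point of delivery could be fitted:\n  %s",
          paste(sprintf("%s: %s", names(errors), errors), collapse = "\n  "))
  }
  dlist <- lapply(decs, function(x) x$decomposition)
  results <- results_long(dlist)
  table <- format_results(dlist)

  files <- character()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    f_res <- file.path(config$output_dir, "results.csv")
    utils::write.csv(results, f_res, row.names = FALSE, quote = FALSE)
    f_rep <- file.path(config$output_dir, "report.md")
    writeLines(c(
      "# Decomposition of total growth by point of delivery",
      "",
      paste0("| ", paste(names(table), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|"),
      apply(table, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
      "",
      "P, S and H intervals are Monte-Carlo intervals treating the four",
      "models' year coefficients as independent normal draws; the models",
      "share data, so this independence is an approximation."
    ), f_rep)
    files <- c(results = f_res, report = f_rep)
    conv <- lapply(decs, function(d) {
      vapply(d$fits, function(f) f$converged, logical(1))
    })
    manifest <- list(
      seed = config$seed,
      input_mode = config$input_mode,
      pods = config$pods,
      baseline_year = baseline,
      basis_df = config$basis_df,
      method = config$method,
      n_sims = config$n_sims,
      level = config$level,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("hospgrowth")),
      convergence = conv,
      files = as.list(tools::md5sum(unname(files)))
    )
    f_man <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE)
    files["manifest"] <- f_man
  }

  list(decompositions = decs, results = results, table = table,
       errors = errors,
       inputs = list(population = pop, lifetable = life, prevalence = prev,
                     activity = act, hsa = hsa),
       files = files)
}

#' Descriptive summary of the study tables
#'
#' Per-year population totals by sex, mean age (90+ lumped at 90), sex
#' ratio, observed prevalence share, and per-pod activity totals by sex
#' -- the overview-table shape of a study-population description.
#'
#' @param population population table.
#' @param prevalence prevalence table (optional).
#' @param activity activity counts over any set of pods (optional).
#' @return long data.frame with columns `measure`, `sex`, `year`, `value`.
#' @export
descriptive_report <- function(population, prevalence = NULL,
                               activity = NULL) {
  rows <- list()
  add <- function(measure, sex, year, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, sex = sex, year = year, value = value,
      stringsAsFactors = FALSE)
  }
  for (g in split(population, list(population$year, population$sex), drop = TRUE)) {
    add("population", g$sex[1], g$year[1], sum(g$count))
    add("mean_age", g$sex[1], g$year[1], sum(g$age * g$count) / sum(g$count))
  }
  for (y in sort(unique(population$year))) {
    py <- population[population$year == y, ]
    add("population", "all", y, sum(py$count))
    add("mean_age", "all", y, sum(py$age * py$count) / sum(py$count))
    add("sex_ratio_m_f", "all", y,
        sum(py$count[py$sex == "m"]) / sum(py$count[py$sex == "f"]))
  }
  if (!is.null(prevalence)) {
    m <- merge(prevalence, population, by = c("year", "age", "sex"))
    for (g in split(m, list(m$year, m$sex), drop = TRUE)) {
      add("prevalence_cms_gt_1_5", g$sex[1], g$year[1],
          sum(g$p * g$count) / sum(g$count))
    }
  }
  if (!is.null(activity)) {
    for (g in split(activity, list(activity$pod, activity$year, activity$sex),
                    drop = TRUE)) {
      add(paste0("activity_", g$pod[1]), g$sex[1], g$year[1], sum(g$count))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$measure, out$sex, out$year), ]
}
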