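# The nested negative-binomial model ladder:
#   M1: activity ~ year
#   M2: activity ~ year + offset(log population)
#   M3: activity ~ year + s(age, by = sex) + offset(log population)
#   M4: activity ~ year + s(health-status age, by = sex) + offset(log population)
# The year coefficient enters linearly; its exponential minus one is the
# annual growth rate captured at that rung of the ladder.

MODEL_IDS <- c("M1", "M2", "M3", "M4")

#' Specification of one model in the ladder
#'
#' @param model_id `"M1"`..`"M4"`.
#' @param pod point of delivery; for maternity the sex variable is
#'   excluded (the data are all-female) and M4 is undefined.
#' @param basis_df spline basis dimension per sex (the `k` of the
#'   penalised smooth, or the `df` of the unpenalised natural-spline
#'   fallback).
#' @param year_reference calendar year at which the year covariate is
#'   centred; defaults to the earliest year in the data at fit time.
#' @param method `"reml"` for a penalised thin-plate smooth with
#'   REML-selected smoothing (the default), or `"ns"` for an unpenalised
#'   natural cubic B-spline basis fitted by alternating NB maximum
#'   likelihood.
#' @return list of class `"model_spec"` with derived fields
#'   `include_offset`, `smooth_covariate` (`"none"`, `"age"` or `"hsa"`)
#'   and `by_sex`.
#' @export
model_spec <- function(model_id, pod, basis_df = 10, year_reference = NULL,
                       method = c("reml", "ns")) {
  model_id <- match.arg(model_id, MODEL_IDS)
  check_pod(pod)
  method <- match.arg(method)
  if (pod == "maternity" && model_id == "M4") {
    stopf("M4 is undefined for the maternity pod: the health-status-age covariate applies at ages 55+ only")
  }
  spec <- list(
    model_id = model_id, pod = pod,
    include_offset = model_id != "M1",
    smooth_covariate = switch(model_id, M1 = "none", M2 = "none",
                              M3 = "age", M4 = "hsa"),
    by_sex = pod != "maternity",
    basis_df = basis_df, year_reference = year_reference, method = method
  )
  class(spec) <- "model_spec"
  spec
}

#' Assemble the model design for one ladder rung
#'
#' Joins the activity counts with the population offsets and, for M4, the
#' health-status-age covariate, centres the year covariate, and drops
#' (with a message) cells whose population is zero, since their log
#' offset is undefined.
#'
#' @param counts activity counts for one pod (`pod`, `year`, `age`, `sex`,
#'   `count`).
#' @param population population table (`year`, `age`, `sex`, `count`);
#'   ignored for M1.
#' @param hsa health-status-age table from [build_hsa_table()]; required
#'   for M4 only.
#' @param spec a [model_spec()].
#' @return data.frame with columns `count`, `year`, `year_c`, `age`,
#'   `sex` (factor), `pop`, `log_pop` and (for M4) `hsa`; the spec is
#'   attached as attribute `"spec"`.
#' @export
build_design <- function(counts, population = NULL, hsa = NULL, spec) {
  stopifnot(inherits(spec, "model_spec"))
  check_columns(counts, c("year", "age", "sex", "count"), "counts")
  d <- counts[, c("year", "age", "sex", "count")]
  if (spec$include_offset) {
    if (is.null(population)) stopf("model %s needs a population table", spec$model_id)
    p <- population[, c("year", "age", "sex", "count")]
    names(p)[4] <- "pop"
    d <- merge(d, p, by = c("year", "age", "sex"))
    if (nrow(d) < nrow(counts)) {
      miss <- merge(counts, p, by = c("year", "age", "sex"), all.x = TRUE)
      miss <- miss[is.na(miss$pop), ]
      stopf("population table does not cover %d count cell(s), e.g. year=%s age=%s sex=%s",
            nrow(miss), miss$year[1], miss$age[1], miss$sex[1])
    }
    zero <- d$pop <= 0
    if (any(zero)) {
      message(sprintf("dropping %d cell(s) with zero population (undefined log offset)",
                      sum(zero)))
      d <- d[!zero, , drop = FALSE]
    }
    d$log_pop <- log(d$pop)
  }
  if (spec$smooth_covariate == "hsa") {
    if (is.null(hsa)) stopf("model M4 needs a health-status-age table")
    h <- hsa[, c("year", "age", "sex", "hsa")]
    d <- merge(d, h, by = c("year", "age", "sex"))
    if (anyNA(d$hsa)) stopf("health-status-age table has gaps on the count grid")
  }
  ref <- if (is.null(spec$year_reference)) min(d$year) else spec$year_reference
  d$year_c <- d$year - ref
  d$sex <- factor(d$sex, levels = SEX_LEVELS[SEX_LEVELS %in% unique(d$sex)])
  d <- d[order(d$year, d$sex, d$age), ]
  rownames(d) <- NULL
  attr(d, "spec") <- spec
  d
}

# build the model formula for a design + spec
.ladder_formula <- function(spec) {
  rhs <- "year_c"
  if (spec$smooth_covariate != "none") {
    v <- if (spec$smooth_covariate == "hsa") "hsa" else "age"
    if (spec$method == "reml") {
      rhs <- if (spec$by_sex) {
        sprintf("%s + sex + s(%s, by = sex, k = %d)", rhs, v, spec$basis_df)
      } else {
        sprintf("%s + s(%s, k = %d)", rhs, v, spec$basis_df)
      }
    } else {
      df <- min(spec$basis_df, 6L)
      basis <- sprintf("splines::ns(%s, df = %d)", v, df)
      rhs <- if (spec$by_sex) {
        sprintf("%s + sex + %s + sex:%s", rhs, basis, basis)
      } else {
        sprintf("%s + %s", rhs, basis)
      }
    }
  }
  if (spec$include_offset) rhs <- paste(rhs, "+ offset(log_pop)")
  stats::as.formula(paste("count ~", rhs))
}

#' Fit one rung of the negative-binomial ladder
#'
#' Maximises the NB likelihood with the year coefficient unpenalised.  The
#' default engine is [mgcv::gam()] with `family = nb()` (dispersion
#' estimated by ML alongside REML smoothing selection); `method = "ns"` in
#' the spec switches to [MASS::glm.nb()] on an unpenalised natural-spline
#' basis.  The standard error of the year coefficient is taken from the
#' observed information of the final fit, with the smoothing parameters
#' treated as fixed (standard GAM practice).
#'
#' @param design output of [build_design()].
#' @param spec the matching [model_spec()]; defaults to the spec attached
#'   to the design.
#' @param fixed_theta optional fixed NB size parameter `theta` (so
#'   dispersion `phi = 1/theta`); by default `theta` is estimated.  A very
#'   large `theta` gives the Poisson limit.
#' @param keep_fit retain the underlying fitted model object.
#' @return object of class `"nb_growth_fit"`: a list with `model_id`,
#'   `pod`, `beta_year` (log annual growth), `se_year`, `dispersion`
#'   (`1/theta`), `log_likelihood`, `converged`, `n_cells`, `method` and
#'   optionally `fit`.
#' @export
fit_nb_spline_model <- function(design, spec = attr(design, "spec"),
                                fixed_theta = NULL, keep_fit = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(unique(design$year_c)) < 2L) {
    stopf("design is degenerate: fewer than 2 distinct years")
  }
  if (all(design$count == 0)) stopf("all-zero response")
  fml <- .ladder_formula(spec)
  if (spec$method == "reml") {
    fam <- if (is.null(fixed_theta)) mgcv::nb() else mgcv::negbin(fixed_theta)
    fit <- mgcv::gam(fml, family = fam, data = design, method = "REML",
                     control = mgcv::gam.control(epsilon = 1e-8, maxit = 200))
    theta <- if (is.null(fixed_theta)) fit$family$getTheta(TRUE) else fixed_theta
    converged <- isTRUE(fit$converged)
  } else {
    if (is.null(fixed_theta)) {
      fit <- suppressWarnings(
        MASS::glm.nb(fml, data = design, control = stats::glm.control(
          epsilon = 1e-8, maxit = 200))
      )
      theta <- fit$theta
      converged <- isTRUE(fit$converged)
    } else {
      fit <- stats::glm(fml, data = design,
                        family = MASS::negative.binomial(fixed_theta),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 200))
      theta <- fixed_theta
      converged <- isTRUE(fit$converged)
    }
  }
  cf <- stats::coef(fit)
  if (!"year_c" %in% names(cf)) stopf("year coefficient missing from fit")
  V <- stats::vcov(fit)
  out <- list(
    model_id = spec$model_id, pod = spec$pod,
    beta_year = unname(cf["year_c"]),
    se_year = sqrt(V["year_c", "year_c"]),
    dispersion = 1 / theta, theta = theta,
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = converged, n_cells = nrow(design),
    method = spec$method
  )
  if (keep_fit) out$fit <- fit
  class(out) <- "nb_growth_fit"
  out
}

#' @export
print.nb_growth_fit <- function(x, ...) {
  cat(sprintf("%s (%s, %s): beta_year = %.6f (se %.6f), annual growth %s, dispersion %.4f%s\n",
              x$model_id, x$pod, x$method, x$beta_year, x$se_year,
              fmt_pct(exp(x$beta_year) - 1), x$dispersion,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Annual growth rate captured by a fitted model
#'
#' The exponentiated year coefficient minus one.
#'
#' @param fit an `"nb_growth_fit"`.
#' @return proportion per year.
#' @export
annual_growth <- function(fit) {
  stopifnot(inherits(fit, "nb_growth_fit"))
  if (!fit$converged) {
    stopf("model %s did not converge; refusing to report a growth rate", fit$model_id)
  }
  exp(fit$beta_year) - 1
}

#' Fit the full model ladder for one point of delivery
#'
#' Fits M1--M4 (M1--M3 for maternity, where the health-status-age
#' covariate is undefined) on the aligned tables.
#'
#' @inheritParams build_design
#' @param pod point of delivery.
#' @param basis_df,year_reference,method passed to [model_spec()].
#' @param keep_fit retain underlying model objects.
#' @return named list of `"nb_growth_fit"` objects.
#' @export
fit_growth_models <- function(counts, population, hsa = NULL, pod,
                              basis_df = 10, year_reference = NULL,
                              method = c("reml", "ns"), keep_fit = TRUE) {
  method <- match.arg(method)
  check_pod(pod)
  ids <- if (pod == "maternity") MODEL_IDS[1:3] else MODEL_IDS
  fits <- lapply(ids, function(id) {
    spec <- model_spec(id, pod, basis_df = basis_df,
                       year_reference = year_reference, method = method)
    des <- build_design(counts, population, hsa, spec)
    fit_nb_spline_model(des, spec, keep_fit = keep_fit)
  })
  stats::setNames(fits, ids)
}
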