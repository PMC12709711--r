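# The central fitting interface: fit the whole ladder for one point of
# delivery and decompose its growth, returning a classed model object.

#' Fit and decompose activity growth for one point of delivery
#'
#' Fits the nested negative-binomial spline ladder (M1--M4; M1--M3 for
#' maternity) to activity counts, then decomposes the total annual growth
#' G into population-size (P), age-sex-structure (S), health-status (H)
#' and residual (R) components with Wald intervals for G and R and
#' Monte-Carlo intervals for P, S and H.
#'
#' @param counts activity counts for the pod (`pod`, `year`, `age`, `sex`,
#'   `count`).
#' @param population population table (`year`, `age`, `sex`, `count`).
#' @param hsa health-status-age table from [build_hsa_table()]; required
#'   except for maternity.
#' @param pod point of delivery; defaults to the single pod present in
#'   `counts`.
#' @param basis_df,year_reference,method passed to [model_spec()].
#' @param n_sims,seed,level Monte-Carlo interval settings.
#' @param keep_fits retain the underlying mgcv/glm fits (needed for
#'   [residuals.pod_growth()]).
#' @return object of class `"pod_growth"` with elements `pod`, `fits`,
#'   `decomposition`, `n_cells`, `years`, `call`.
#' @examples
#' \donttest{
#' cfg <- generator_config(base_population = 3000, seed = 7)
#' pop <- generate_population(cfg)
#' life <- generate_life_tables(cfg)
#' prev <- generate_prevalence(cfg)
#' hsa <- build_hsa_table(life, prev, cfg$baseline_year)
#' cnt <- generate_activity_counts(cfg, pop, "elective")
#' fit <- pod_growth(cnt, pop, hsa, n_sims = 500, seed = 1)
#' fit
#' coef(fit)
#' }
#' @export
pod_growth <- function(counts, population, hsa = NULL, pod = NULL,
                       basis_df = 10, year_reference = NULL,
                       method = c("reml", "ns"), n_sims = 1000, seed = 1L,
                       level = 0.95, keep_fits = TRUE) {
  method <- match.arg(method)
  if (is.null(pod)) {
    pods <- unique(counts$pod)
    if (length(pods) != 1L) stopf("`counts` holds %d pods; supply `pod`", length(pods))
    pod <- pods
  }
  check_pod(pod)
  counts <- counts[counts$pod == pod, , drop = FALSE]
  fits <- fit_growth_models(counts, population, hsa, pod,
                            basis_df = basis_df,
                            year_reference = year_reference,
                            method = method, keep_fit = keep_fits)
  dec <- decompose_growth(fits, pod = pod, n_sims = n_sims, seed = seed,
                          level = level)
  out <- list(pod = pod, fits = fits, decomposition = dec,
              n_cells = fits[[1]]$n_cells,
              years = sort(unique(counts$year)), call = match.call())
  class(out) <- "pod_growth"
  out
}

#' @export
print.pod_growth <- function(x, ...) {
  cat(sprintf("Hospital activity growth decomposition -- %s (%d-%d, %d cells)\n",
              x$pod, min(x$years), max(x$years), x$n_cells))
  print(x$decomposition)
  invisible(x)
}

#' @export
summary.pod_growth <- function(object, ...) {
  mods <- do.call(rbind, lapply(object$fits, function(f) {
    data.frame(model = f$model_id, beta_year = f$beta_year,
               se_year = f$se_year, annual_growth = exp(f$beta_year) - 1,
               dispersion = f$dispersion, logLik = f$log_likelihood,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  rownames(mods) <- NULL
  out <- list(pod = object$pod, models = mods,
              decomposition = object$decomposition,
              table = format_results(object$decomposition))
  class(out) <- "summary.pod_growth"
  out
}

#' @export
print.summary.pod_growth <- function(x, ...) {
  cat(sprintf("Model ladder -- %s\n", x$pod))
  print(x$models, digits = 5)
  cat("\n")
  print(x$decomposition)
  invisible(x)
}

#' @export
coef.pod_growth <- function(object, ...) {
  object$decomposition$estimates
}

#' @export
confint.pod_growth <- function(object, parm, level, ...) {
  ci <- object$decomposition$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate component draws from a fitted decomposition
#'
#' Redraws the year coefficients from their estimated normal
#' distributions (independently across models, as in the interval
#' procedure) and returns the implied component growth rates per draw.
#'
#' @param object a `"pod_growth"` fit.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with columns `G`, `P`, `S`, (`H`,) `R`, one row per
#'   draw.
#' @export
simulate.pod_growth <- function(object, nsim = 1000, seed = 1L, ...) {
  fits <- object$fits
  maternity <- object$pod == "maternity"
  draws <- with_seed(seed, {
    lapply(fits, function(f) stats::rnorm(nsim, f$beta_year, f$se_year))
  })
  b4 <- if (maternity) draws$M3 else draws$M4
  out <- data.frame(
    G = exp(draws$M1) - 1,
    P = exp(draws$M1 - draws$M2) - 1,
    S = exp(draws$M2 - draws$M3) - 1
  )
  if (!maternity) out$H <- exp(draws$M3 - draws$M4) - 1
  out$R <- exp(b4) - 1
  out
}

#' @export
residuals.pod_growth <- function(object, model = NULL, type = "deviance", ...) {
  if (is.null(model)) model <- utils::tail(names(object$fits), 1L)
  f <- object$fits[[model]]
  if (is.null(f$fit)) {
    stopf("underlying fits were not kept; refit with keep_fits = TRUE")
  }
  stats::residuals(f$fit, type = type)
}

#' Plot a growth decomposition
#'
#' Dot-and-whisker display of the G, P, S, H and R estimates with their
#' intervals, one panel per fitted object.
#'
#' @param x a `"pod_growth"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pod_growth <- function(x, ...) {
  d <- x$decomposition
  est <- 100 * d$estimates
  ci <- 100 * d$ci
  k <- length(est)
  ylim <- range(c(est, ci), na.rm = TRUE)
  graphics::plot(seq_len(k), est, xaxt = "n", xlab = "",
                 ylab = "annual growth (%)", pch = 19, xlim = c(0.5, k + 0.5),
                 ylim = ylim + c(-0.1, 0.1) * diff(ylim),
                 main = sprintf("Growth decomposition: %s", x$pod), ...)
  graphics::axis(1, at = seq_len(k), labels = names(est))
  graphics::abline(h = 0, lty = 3, col = "grey50")
  ok <- !is.na(ci[, "low"])
  graphics::arrows(seq_len(k)[ok], ci[ok, "low"], seq_len(k)[ok],
                   ci[ok, "high"], angle = 90, code = 3, length = 0.05)
  invisible(x)
}
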