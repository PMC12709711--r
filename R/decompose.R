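# Telescoping decomposition of total growth into components:
#   G = exp(b1) - 1            total growth          (model M1)
#   P = exp(b1 - b2) - 1       population size       (M1 vs M2)
#   S = exp(b2 - b3) - 1       age-sex structure     (M2 vs M3)
#   H = exp(b3 - b4) - 1       age-specific health   (M3 vs M4)
#   R = exp(b4) - 1            residual              (M4)
# so that (1+P)(1+S)(1+H)(1+R) - 1 = exp(b1) - 1 = G identically.
# Maternity has no M4 (H is disregarded): H = 0 and R comes from M3.

#' Total growth from its components
#'
#' The multiplicative growth identity
#' `G = (1 + P)(1 + S)(1 + H)(1 + R) - 1`.
#'
#' @param P,S,H,R component growth rates, proportions per year.
#' @return total growth G, proportion per year.
#' @examples
#' compute_total_growth(0.0088, 0.0069, -0.0003, 0.0073)  # ~0.0229
#' @export
compute_total_growth <- function(P, S, H, R) {
  (1 + P) * (1 + S) * (1 + H) * (1 + R) - 1
}

.check_fits <- function(fits, pod) {
  need <- if (pod == "maternity") MODEL_IDS[1:3] else MODEL_IDS
  missing <- setdiff(need, names(fits))
  if (length(missing)) {
    stopf("missing model fit(s): %s", paste(missing, collapse = ", "))
  }
  for (id in need) {
    f <- fits[[id]]
    if (!inherits(f, "nb_growth_fit")) stopf("fits$%s is not an nb_growth_fit", id)
    if (!f$converged) stopf("model %s did not converge; decomposition refused", id)
  }
  fits[need]
}

#' Wald confidence interval on the growth scale
#'
#' `exp(beta +/- z * se) - 1` for the year coefficient of a single model;
#' used for the components identified by one coefficient (G from M1, R
#' from the deepest model).
#'
#' @param fit an `"nb_growth_fit"`, or a bare numeric `beta` when `se` is
#'   given.
#' @param level confidence level.
#' @param se standard error (taken from `fit` when omitted).
#' @return numeric vector `c(low, high)` of growth rates.
#' @export
wald_ci <- function(fit, level = 0.95, se = NULL) {
  if (inherits(fit, "nb_growth_fit")) {
    beta <- fit$beta_year
    if (is.null(se)) se <- fit$se_year
  } else {
    beta <- fit
    if (is.null(se)) stopf("`se` must be supplied when `fit` is a bare coefficient")
  }
  if (!is.finite(se) || se < 0) stopf("standard error must be non-negative and finite")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = exp(beta - z * se) - 1, high = exp(beta + z * se) - 1)
}

#' Monte-Carlo confidence intervals for the ratio components P, S, H
#'
#' Each year coefficient is drawn independently from a normal distribution
#' with its estimated mean and standard error; the component growth rates
#' `exp(b_a - b_b) - 1` are formed per draw and their empirical 2.5% and
#' 97.5% quantiles (at `level = 0.95`) reported.  Central estimates remain
#' the algebraic ones.  Draws are independent across models -- the four
#' models share data, so their coefficients are in truth correlated; this
#' independence approximation is deliberate and flagged in the report.
#'
#' @param fits named list of `"nb_growth_fit"` objects (`M1`..`M4`, or
#'   `M1`..`M3` for maternity).
#' @param n_sims number of draws (default 1000).
#' @param seed integer seed; draws are deterministic given it.
#' @param level confidence level.
#' @param pod point of delivery (maternity skips H).
#' @return list with per-component elements `P`, `S` (and `H` unless
#'   maternity), each `c(low, high)`, plus `draws` (data.frame of the
#'   simulated component values) and `se` (Monte-Carlo standard
#'   deviations of the component draws).
#' @export
monte_carlo_ci <- function(fits, n_sims = 1000, seed = 1L, level = 0.95,
                           pod = fits[[1]]$pod) {
  fits <- .check_fits(fits, pod)
  if (n_sims < 100) warnf("n_sims = %d is small; intervals will be unstable", n_sims)
  draws <- with_seed(seed, {
    lapply(fits, function(f) stats::rnorm(n_sims, f$beta_year, f$se_year))
  })
  comp <- list(P = exp(draws$M1 - draws$M2) - 1,
               S = exp(draws$M2 - draws$M3) - 1)
  if (pod != "maternity") comp$H <- exp(draws$M3 - draws$M4) - 1
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- lapply(comp, function(x) {
    stats::setNames(stats::quantile(x, probs, names = FALSE), c("low", "high"))
  })
  out$draws <- as.data.frame(comp)
  out$se <- vapply(comp, stats::sd, numeric(1))
  out
}

#' Decompose fitted growth into P, S, H and R
#'
#' Converts the year coefficients of the fitted ladder into the
#' multiplicative components, with Wald intervals for G and R and
#' Monte-Carlo intervals for P, S and H.  For maternity, H is disregarded
#' (set to 0 with no interval) and R is taken from M3, the deepest defined
#' model.
#'
#' @param fits named list of `"nb_growth_fit"` objects.
#' @param pod point of delivery.
#' @param n_sims Monte-Carlo draws for the ratio components.
#' @param seed seed for the Monte-Carlo draws.
#' @param level confidence level.
#' @return object of class `"growth_decomposition"`: a list with
#'   `estimates` (named vector G/P/S/H/R), `ci` (matrix with rows
#'   G/P/S/H/R and columns low/high; NA for maternity H), `ci_method`,
#'   `mc_se`, `pod`, `n_sims`, `seed`, `level`.
#' @export
decompose_growth <- function(fits, pod = fits[[1]]$pod, n_sims = 1000,
                             seed = 1L, level = 0.95) {
  check_pod(pod)
  fits <- .check_fits(fits, pod)
  b <- vapply(fits, function(f) f$beta_year, numeric(1))
  maternity <- pod == "maternity"
  b4 <- if (maternity) b[["M3"]] else b[["M4"]]
  est <- c(
    G = exp(b[["M1"]]) - 1,
    P = exp(b[["M1"]] - b[["M2"]]) - 1,
    S = exp(b[["M2"]] - b[["M3"]]) - 1,
    H = if (maternity) 0 else exp(b[["M3"]] - b[["M4"]]) - 1,
    R = exp(b4) - 1
  )
  mc <- monte_carlo_ci(fits, n_sims = n_sims, seed = seed, level = level,
                       pod = pod)
  ci <- matrix(NA_real_, 5, 2, dimnames = list(names(est), c("low", "high")))
  ci["G", ] <- wald_ci(fits$M1, level)
  ci["R", ] <- wald_ci(if (maternity) fits$M3 else fits$M4, level)
  ci["P", ] <- mc$P
  ci["S", ] <- mc$S
  if (!maternity) ci["H", ] <- mc$H
  ci_method <- c(G = "wald", P = "monte_carlo", S = "monte_carlo",
                 H = if (maternity) "not_applicable" else "monte_carlo",
                 R = "wald")
  out <- list(estimates = est, ci = ci, ci_method = ci_method,
              mc_se = mc$se, pod = pod, n_sims = n_sims, seed = seed,
              level = level)
  class(out) <- "growth_decomposition"
  out
}

#' @export
print.growth_decomposition <- function(x, ...) {
  cat(sprintf("Growth decomposition: %s\n", x$pod))
  for (k in names(x$estimates)) {
    if (x$ci_method[[k]] == "not_applicable") {
      cat(sprintf("  %s = %s (NA)\n", k, fmt_pct(x$estimates[[k]])))
    } else {
      cat(sprintf("  %s = %s (%s to %s) [%s]\n", k, fmt_pct(x$estimates[[k]]),
                  fmt_pct(x$ci[k, "low"]), fmt_pct(x$ci[k, "high"]),
                  x$ci_method[[k]]))
    }
  }
  invisible(x)
}

#' Format decompositions as a report table
#'
#' One row per point of delivery with G, P, S, H and R rendered as
#' percentages to two decimal places (half-away-from-zero) with their
#' interval strings, the shape used for publication tables.  A maternity H
#' renders as `"0.00% (NA)"`.
#'
#' @param decompositions list of `"growth_decomposition"` objects (or a
#'   single one).
#' @return data.frame of formatted strings with a `pod` column.
#' @export
format_results <- function(decompositions) {
  if (inherits(decompositions, "growth_decomposition")) {
    decompositions <- list(decompositions)
  }
  if (length(decompositions) == 0L) {
    return(data.frame(pod = character(), G = character(), P = character(),
                      S = character(), H = character(), R = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(decompositions, function(d) {
    cells <- vapply(names(d$estimates), function(k) {
      if (d$ci_method[[k]] == "not_applicable") {
        sprintf("%s (NA)", fmt_pct(d$estimates[[k]]))
      } else {
        sprintf("%s (%s to %s)", fmt_pct(d$estimates[[k]]),
                fmt_pct(d$ci[k, "low"]), fmt_pct(d$ci[k, "high"]))
      }
    }, character(1))
    data.frame(pod = d$pod, t(cells), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format decomposition results
#'
#' @param decompositions list of `"growth_decomposition"` objects.
#' @return data.frame with columns `pod`, `component`, `estimate`,
#'   `ci_low`, `ci_high`, `ci_method`.
#' @export
results_long <- function(decompositions) {
  if (inherits(decompositions, "growth_decomposition")) {
    decompositions <- list(decompositions)
  }
  rows <- lapply(decompositions, function(d) {
    data.frame(pod = d$pod, component = names(d$estimates),
               estimate = unname(d$estimates),
               ci_low = unname(d$ci[, "low"]),
               ci_high = unname(d$ci[, "high"]),
               ci_method = unname(d$ci_method),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
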