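# Sullivan-method disability-free life expectancy and the health-status-age
# transform.
#
# "Disability-free" means a Cambridge Multimorbidity Score below 1.5.  The
# Sullivan method weights each life-table age interval's person-years by the
# proportion free of major illness:
#
#   dfle(i) = sum_{x >= i} Lx * (1 - p_x) / l_i
#
# Health-status age adjusts chronological age i (55+ only, and only after
# the baseline year) by the change in dfle since baseline, scaled by the
# change in life expectancy at i relative to the change at the reference
# age 65:
#
#   hsa(i, y) = i - (dfle_{i,y} - dfle_{i,base}) *
#                   (le_{i,y} - le_{i,base}) / (le_{65,y} - le_{65,base})

#' Sullivan-method disability-free life expectancy
#'
#' @param life life table (columns `year`, `age` 0..90, `sex`, `lx`, `Lx`,
#'   `ex`); the age-90 row is the open interval, its `Lx` holding all
#'   remaining person-years.
#' @param prev prevalence table (columns `year`, `age`, `sex`, `p`), the
#'   proportion with major illness (CMS > 1.5), on the same grid.
#' @return data.frame with columns `year`, `age`, `sex`, `dfle` (years).
#' @examples
#' life <- data.frame(year = 2011, age = 0:2, sex = "f",
#'                    lx = c(1000, 600, 200), Lx = c(800, 400, 300),
#'                    ex = c(1.5, 7/6, 1.5))
#' prev <- data.frame(year = 2011, age = 0:2, sex = "f", p = c(0, 0.5, 1))
#' sullivan_dfle(life, prev)  # dfle at age 0 is 1.0 years
#' @export
sullivan_dfle <- function(life, prev) {
  check_columns(life, c("year", "age", "sex", "lx", "Lx"), "life table")
  check_columns(prev, c("year", "age", "sex", "p"), "prevalence table")
  if (any(prev$p < 0 | prev$p > 1, na.rm = TRUE)) {
    stopf("prevalence values outside [0, 1]")
  }
  m <- merge(life, prev[, c("year", "age", "sex", "p")],
             by = c("year", "age", "sex"))
  if (nrow(m) < nrow(life)) {
    miss <- merge(life, prev[, c("year", "age", "sex", "p")],
                  by = c("year", "age", "sex"), all.x = TRUE)
    miss <- miss[is.na(miss$p), c("year", "age", "sex")]
    stopf("prevalence table is missing %d cell(s), e.g. year=%s age=%s sex=%s",
          nrow(miss), miss$year[1], miss$age[1], miss$sex[1])
  }
  m <- m[order(m$year, m$sex, m$age), ]
  out <- do.call(rbind, lapply(split(m, list(m$year, m$sex), drop = TRUE),
    function(g) {
      healthy_py <- rev(cumsum(rev(g$Lx * (1 - g$p))))
      data.frame(year = g$year, age = g$age, sex = g$sex,
                 dfle = healthy_py / g$lx, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$year, out$sex, out$age), ]
}

#' Health-status age for one or more cells
#'
#' Below `min_adjust_age` (default 55) and in the baseline year,
#' health-status age equals chronological age.  Otherwise it is the
#' chronological age minus the change in disability-free life expectancy
#' since baseline, multiplied by the change in life expectancy at that age
#' relative to the change at `ref_age` (default 65).  When life expectancy
#' at `ref_age` has not changed since baseline (denominator below
#' `guard_tol`), the scaling bracket is set to 1 so the dfle signal is
#' retained rather than dividing by ~0; the event is recorded in the
#' `"guard_events"` attribute of [build_hsa_table()] output.
#'
#' @param i chronological age(s), integer 0..90.
#' @param sex `"f"`/`"m"`, recycled against `i`.
#' @param year calendar year(s), recycled.
#' @param dfle table from [sullivan_dfle()].
#' @param life the matching life table.
#' @param baseline_year baseline calendar year.
#' @param min_adjust_age youngest age at which adjustment applies.
#' @param ref_age age anchoring the life-expectancy denominator.
#' @param guard_tol tolerance (years) below which the denominator counts
#'   as unchanged.
#' @return numeric vector of health-status ages (years, real-valued).
#' @export
health_status_age <- function(i, sex, year, dfle, life, baseline_year,
                              min_adjust_age = 55, ref_age = 65,
                              guard_tol = 1e-9) {
  n <- max(length(i), length(sex), length(year))
  i <- rep_len(i, n); sex <- rep_len(sex, n); year <- rep_len(year, n)
  key <- function(df, col) {
    stats::setNames(df[[col]], paste(df$year, df$age, df$sex))
  }
  dk <- key(dfle, "dfle")
  ek <- key(life, "ex")
  lookup <- function(tab, year, age, sex, what) {
    v <- tab[paste(year, age, sex)]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stopf("%s lookup failed for year=%s age=%s sex=%s",
            what, year[bad], age[bad], sex[bad])
    }
    unname(v)
  }
  out <- as.numeric(i)
  adj <- i >= min_adjust_age & year != baseline_year
  if (any(adj)) {
    ia <- i[adj]; sa <- sex[adj]; ya <- year[adj]
    d_dfle <- lookup(dk, ya, ia, sa, "dfle") -
      lookup(dk, baseline_year, ia, sa, "dfle")
    d_le <- lookup(ek, ya, ia, sa, "life expectancy") -
      lookup(ek, baseline_year, ia, sa, "life expectancy")
    d_le65 <- lookup(ek, ya, ref_age, sa, "life expectancy") -
      lookup(ek, baseline_year, ref_age, sa, "life expectancy")
    bracket <- ifelse(abs(d_le65) < guard_tol, 1, d_le / d_le65)
    out[adj] <- ia - d_dfle * bracket
  }
  out
}

#' Health-status age over the full grid
#'
#' Applies [health_status_age()] to every (year, age, sex) cell of the
#' life table, returning the covariate table used by the health-status
#' model (M4).
#'
#' @param life life table (see [sullivan_dfle()]).
#' @param prev prevalence table.
#' @param baseline_year baseline calendar year.
#' @param smooth_prevalence if `TRUE`, apply a 3-age moving average to the
#'   observed prevalence before the Sullivan computation (off by default;
#'   the year-stratified sample estimates are otherwise used as-is).
#' @inheritParams health_status_age
#' @return data.frame with columns `year`, `age`, `sex`, `hsa`, plus
#'   attributes `"diagnostics"` (min/max adjustment by year and sex) and
#'   `"guard_events"` (count of zero-denominator guard activations).
#' @export
build_hsa_table <- function(life, prev, baseline_year,
                            min_adjust_age = 55, ref_age = 65,
                            guard_tol = 1e-9, smooth_prevalence = FALSE) {
  if (smooth_prevalence) {
    prev <- prev[order(prev$year, prev$sex, prev$age), ]
    prev$p <- stats::ave(prev$p, prev$year, prev$sex, FUN = function(x) {
      sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
      ifelse(is.na(sm), x, as.numeric(sm))
    })
  }
  dfle <- sullivan_dfle(life, prev)
  grid <- life[, c("year", "age", "sex")]
  hsa <- health_status_age(grid$age, grid$sex, grid$year, dfle, life,
                           baseline_year, min_adjust_age, ref_age, guard_tol)
  if (any(!is.finite(hsa))) stopf("non-finite health-status age produced")
  out <- cbind(grid, hsa = hsa)
  # count zero-denominator guard activations across (year != baseline, sex)
  ex65 <- life[life$age == ref_age, ]
  base65 <- ex65[ex65$year == baseline_year, ]
  later65 <- ex65[ex65$year != baseline_year, ]
  d65 <- later65$ex - base65$ex[match(later65$sex, base65$sex)]
  attr(out, "guard_events") <- sum(abs(d65) < guard_tol)
  diag <- do.call(rbind, lapply(split(out, list(out$year, out$sex), drop = TRUE),
    function(g) data.frame(year = g$year[1], sex = g$sex[1],
                           min_adjust = min(g$age - g$hsa),
                           max_adjust = max(g$age - g$hsa))))
  rownames(diag) <- NULL
  attr(out, "diagnostics") <- diag
  rownames(out) <- NULL
  out
}
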