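# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state, so
#' seeded draws inside the package never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero, the convention used for percentage display
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a percentage string
#'
#' @param x proportion (0.0229 prints as "2.29%").
#' @param digits decimal places (half-away-from-zero rounding).
#' @return character vector.
#' @keywords internal
#' @noRd
fmt_pct <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round_half_away(100 * x, digits))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# assert that a data frame has the given columns
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

POD_LEVELS <- c("elective", "non_elective", "maternity", "outpatient", "ed")
SEX_LEVELS <- c("f", "m")
MATERNITY_AGES <- 15:49

check_pod <- function(pod) {
  if (length(pod) != 1L || !pod %in% POD_LEVELS) {
    stopf("`pod` must be one of: %s", paste(POD_LEVELS, collapse = ", "))
  }
  pod
}
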