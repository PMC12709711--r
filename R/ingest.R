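# Record-level ingest: classify events into points of delivery, apply the
# inclusion/exclusion rules, and aggregate to the analysis grid.

#' Classify event records into points of delivery
#'
#' Inpatient records are mapped through the admission-method field
#' (defaults: elective 11/12/13, non-elective 21--25/2A--2D/28, maternity
#' 31/32 -- the national data-dictionary groupings); outpatient and ED
#' records keep their stream label.  Records with an unknown admission
#' method are classified `"excluded"` with a warning, never an error.
#'
#' @param records data.frame of event records with at least `pod_raw`
#'   (`"inpatient"`, `"outpatient"`, `"ed"`) and `admission_method`.
#' @param code_map named list of admission-method code vectors for
#'   `elective`, `non_elective` and `maternity`.
#' @return character vector of pod labels (or `"excluded"`), one per record.
#' @export
classify_pod <- function(records, code_map = ADMISSION_METHOD_CODES) {
  check_columns(records, c("pod_raw", "admission_method"), "records")
  out <- rep(NA_character_, nrow(records))
  out[records$pod_raw == "outpatient"] <- "outpatient"
  out[records$pod_raw == "ed"] <- "ed"
  inp <- records$pod_raw == "inpatient"
  am <- records$admission_method
  for (p in c("elective", "non_elective", "maternity")) {
    out[inp & am %in% code_map[[p]]] <- p
  }
  unknown <- inp & is.na(out)
  if (any(unknown)) {
    warnf("%d inpatient record(s) with unknown admission-method code(s) %s excluded",
          sum(unknown),
          paste(unique(am[unknown]), collapse = ", "))
    out[unknown] <- "excluded"
  }
  bad_stream <- is.na(out)
  if (any(bad_stream)) {
    warnf("%d record(s) with unknown source stream excluded", sum(bad_stream))
    out[bad_stream] <- "excluded"
  }
  out
}

#' Apply the record-level exclusion rules
#'
#' Removes, in order and tallying each record under the first rule it
#' trips: records already classified `"excluded"` (unknown codes);
#' outpatient records whose planned attendance did not occur
#' (attendance-status codes 2, 3, 4, 7); ED attendances outside type 1
#' (multi-specialty consultant-led) departments; records for patients not
#' resident in England; records without a valid age (integer 0..120) or
#' sex ("f"/"m"); maternity records outside females aged 15--49.
#' Well-baby activity (treatment function 424) is retained.
#'
#' @param records data.frame of event records; a `pod` column is added via
#'   [classify_pod()] if absent.
#' @param code_map passed to [classify_pod()] when classification is needed.
#' @return the retained records, with attribute `"removed"`: a named
#'   integer tally of removals per rule.
#' @export
apply_exclusions <- function(records, code_map = ADMISSION_METHOD_CODES) {
  if (!"pod" %in% names(records)) {
    records$pod <- classify_pod(records, code_map)
  }
  rules <- c(unknown_code = NA, opa_status = NA, ed_type = NA,
             non_england = NA, invalid_age_sex = NA, maternity_scope = NA)
  tally <- stats::setNames(integer(length(rules)), names(rules))
  drop <- rep(FALSE, nrow(records))

  mark <- function(rule, hit) {
    hit <- hit & !drop
    tally[[rule]] <<- sum(hit)
    drop <<- drop | hit
  }
  mark("unknown_code", records$pod == "excluded")
  mark("opa_status", records$pod == "outpatient" &
         records$attendance_status %in% c("2", "3", "4", "7"))
  mark("ed_type", records$pod == "ed" &
         (is.na(records$department_type) | records$department_type != "1"))
  mark("non_england", is.na(records$resident_in_england) |
         !records$resident_in_england)
  valid_age <- !is.na(records$age) & records$age == round(records$age) &
    records$age >= 0 & records$age <= 120
  valid_sex <- !is.na(records$sex) & records$sex %in% SEX_LEVELS
  mark("invalid_age_sex", !(valid_age & valid_sex))
  mark("maternity_scope", records$pod == "maternity" &
         !(records$sex == "f" & records$age >= 15 & records$age <= 49))

  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- tally
  out
}

#' Aggregate filtered event records to activity counts
#'
#' Counts events by (pod, year, age, sex), lumping ages above 90 into the
#' open 90+ group (coded 90), and materialises structural zeros over the
#' full analysis grid -- every (year, age 0..90, sex) cell per pod, with
#' the maternity grid restricted to females aged 15--49 -- so that
#' downstream regressions see the complete grid.
#'
#' @param records filtered records from [apply_exclusions()].
#' @param years calendar years of the grid; defaults to the range present.
#' @return data.frame with columns `pod`, `year`, `age`, `sex`, `count`.
#' @export
aggregate_counts <- function(records, years = NULL) {
  if (nrow(records) == 0L) {
    warnf("no records to aggregate; returning an empty table")
    return(data.frame(pod = character(), year = integer(), age = integer(),
                      sex = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  records$age <- pmin(records$age, 90L)
  pods <- intersect(POD_LEVELS, unique(records$pod))
  out <- do.call(rbind, lapply(pods, function(p) {
    grid <- if (p == "maternity") {
      expand.grid(year = years, age = MATERNITY_AGES, sex = "f",
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(year = years, age = 0:90, sex = SEX_LEVELS,
                  stringsAsFactors = FALSE)
    }
    rp <- records[records$pod == p, , drop = FALSE]
    agg <- stats::aggregate(list(count = rep(1L, nrow(rp))),
                            rp[, c("year", "age", "sex")], sum)
    m <- merge(grid, agg, by = c("year", "age", "sex"), all.x = TRUE)
    m$count[is.na(m$count)] <- 0L
    cbind(pod = p, m[order(m$year, m$sex, m$age), ])
  }))
  rownames(out) <- NULL
  out[, c("pod", "year", "age", "sex", "count")]
}

#' Ingest event records end-to-end
#'
#' Convenience wrapper: classify, filter and aggregate in one call.
#'
#' @inheritParams apply_exclusions
#' @inheritParams aggregate_counts
#' @return activity counts (see [aggregate_counts()]) with attribute
#'   `"removed"` carrying the per-rule exclusion tally.
#' @export
ingest_events <- function(records, years = NULL,
                          code_map = ADMISSION_METHOD_CODES) {
  kept <- apply_exclusions(records, code_map)
  out <- aggregate_counts(kept, years)
  attr(out, "removed") <- attr(kept, "removed")
  out
}
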