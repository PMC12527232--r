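#' Exact (Garwood) Poisson confidence limits for a count
#'
#' Chi-square-based exact limits: lower `qchisq(alpha/2, 2k)/2` (0 when
#' k = 0), upper `qchisq(1 - alpha/2, 2k + 2)/2`. Valid at the small counts
#' of rare procedures, where the normal approximation is not.
#'
#' @param count Nonnegative integer count(s).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `count`, `lower`, `upper` (on the count
#'   scale; divide by exposure for rate limits).
#' @export
poisson_count_ci <- function(count, conf_level = 0.95) {
  if (any(!is.finite(count)) || any(count < 0) || any(count != round(count))) {
    abort("`count` must be nonnegative integer(s).")
  }
  alpha <- 1 - conf_level
  lower <- ifelse(count == 0, 0, qchisq(alpha / 2, 2 * count) / 2)
  upper <- qchisq(1 - alpha / 2, 2 * count + 2) / 2
  tibble::tibble(count = count, lower = lower, upper = upper)
}

#' Person-year exposure of a claims enrollment table
#'
#' Sums enrollee coverage days over a 365-day year (2019 is not a leap
#' year). The reference cohort's exposure is instead its census population
#' times one year -- the population is treated as constant over the year --
#' and comes from [restrict_population()].
#'
#' @param enrollment Tibble with a `coverage_days` column (one row per
#'   enrollee), each value in \[0, 365\].
#' @return One-row tibble: `cohort` ("claims"), `person_years`,
#'   `n_individuals`.
#' @export
#' @examples
#' compute_person_years(tibble::tibble(coverage_days = c(365, 182)))
compute_person_years <- function(enrollment) {
  assert_columns(enrollment, "coverage_days", "enrollment")
  cd <- enrollment$coverage_days
  bad <- which(!is.finite(cd) | cd < 0 | cd > 365)
  if (length(bad) > 0L) {
    abort(sprintf(
      "`coverage_days` outside [0, 365] at row(s): %s.",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  tibble::tibble(
    cohort = "claims",
    person_years = sum(cd) / 365,
    n_individuals = nrow(enrollment)
  )
}

#' Estimate event rates with exact Poisson confidence intervals
#'
#' Rate = count / person-years; the 95% interval is the exact Garwood
#' interval on the count divided by the person-years (exposure treated as a
#' known constant).
#'
#' @param counts Tibble with columns `procedure_id` and `count`, one row per
#'   procedure.
#' @param person_years Positive scalar exposure shared by all rows, or a
#'   one-row exposure tibble from [compute_person_years()] /
#'   [restrict_population()].
#' @param conf_level Confidence level.
#' @return A tibble: `procedure_id`, `count`, `person_years`, `rate`,
#'   `ci_low`, `ci_high` (rates in events per person-year).
#' @export
estimate_rates <- function(counts, person_years, conf_level = 0.95) {
  assert_columns(counts, c("procedure_id", "count"), "counts")
  if (is.data.frame(person_years)) person_years <- person_years$person_years
  assert_scalar_number(person_years, "person_years", lower = 0,
                       strict_lower = TRUE)
  ci <- poisson_count_ci(counts$count, conf_level)
  tibble::tibble(
    procedure_id = counts$procedure_id,
    count = as.numeric(counts$count),
    person_years = person_years,
    rate = counts$count / person_years,
    ci_low = ci$lower / person_years,
    ci_high = ci$upper / person_years
  )
}

#' @rdname estimate_rates
#' @param count Single nonnegative count.
#' @param procedure_id Label for the one-row result.
#' @export
estimate_rate <- function(count, person_years, conf_level = 0.95,
                          procedure_id = "overall") {
  estimate_rates(
    tibble::tibble(procedure_id = procedure_id, count = count),
    person_years, conf_level
  )
}

#' Restrict reference discharges and population to a target population
#'
#' Filters the per-stratum reference discharge counts and the census
#' population denominators to a target population, consistently on both
#' sides: `all` keeps every stratum, `insured` keeps commercial + medicaid,
#' `commercial` keeps commercial only.
#'
#' @param reference_discharges Tibble (zip_id, procedure_id, stratum, count).
#' @param zip_areas Tibble from [generate_zip_areas()] (or the same schema).
#' @param target `"all"`, `"insured"`, or `"commercial"`.
#' @return A list: `counts` (tibble procedure_id, count, totalled over the
#'   kept strata and zips) and `exposure` (one-row tibble cohort
#'   ("reference"), person_years = kept population, n_individuals).
#' @export
restrict_population <- function(reference_discharges, zip_areas,
                                target = c("all", "insured", "commercial")) {
  target <- match.arg(target)
  assert_columns(reference_discharges,
                 c("zip_id", "procedure_id", "stratum", "count"),
                 "reference_discharges")
  assert_columns(zip_areas, c("zip_id", "pop_commercial", "pop_medicaid",
                              "pop_uninsured"), "zip_areas")
  bad <- setdiff(unique(reference_discharges$stratum), STRATA)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown stratum label(s): %s.", paste(bad, collapse = ", ")))
  }
  strata <- target_strata(target)

  counts <- reference_discharges |>
    dplyr::filter(.data$stratum %in% strata) |>
    dplyr::group_by(.data$procedure_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  pop <- sum(sapply(strata, function(s) sum(zip_areas[[paste0("pop_", s)]])))
  list(
    counts = counts,
    exposure = tibble::tibble(
      cohort = "reference",
      person_years = pop, # population x 1 year, constant over the year
      n_individuals = as.integer(pop)
    )
  )
}
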