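#' Generate synthetic zip-code areas with SDOH-dependent insurance mix
#'
#' Draws a set of zip-code areas, each with a continuous social-determinants-
#' of-health (SDOH) score and a population split across three insurance
#' strata (commercial, medicaid, uninsured). Higher SDOH means more deprived
#' (the Neighborhood Deprivation Index orientation), and the commercial share
#' of each zip's population *decreases* with SDOH through a logistic link, so
#' deprived areas are under-represented in any cohort sampled from the
#' commercial stratum.
#'
#' @param n_zips Number of zip areas to generate.
#' @param mean_zip_population Mean total population per zip. Populations are
#'   drawn lognormal around this mean (`population_sdlog` on the log scale)
#'   so large and small zips coexist, as in census data.
#' @param sdoh_sd Standard deviation of the SDOH score (mean is 0).
#' @param commercial_share_slope Strength of the decline of the commercial
#'   share with SDOH: the share is
#'   `plogis(qlogis(commercial_share_base) - commercial_share_slope * sdoh)`.
#'   0 gives every zip the same share.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param commercial_share_base Commercial share at SDOH = 0.
#' @param medicaid_share_of_rest Fraction of the non-commercial remainder
#'   assigned to medicaid (the rest is uninsured).
#' @param population_sdlog Log-scale SD of the zip population distribution.
#'
#' @return A tibble with columns `zip_id`, `pop_commercial`, `pop_medicaid`,
#'   `pop_uninsured`, `sdoh`.
#' @export
#' @examples
#' generate_zip_areas(n_zips = 5, seed = 1)
generate_zip_areas <- function(n_zips,
                               mean_zip_population = 8000,
                               sdoh_sd = 1,
                               commercial_share_slope = 1,
                               seed,
                               commercial_share_base = 0.72,
                               medicaid_share_of_rest = 0.64,
                               population_sdlog = 0.5) {
  n_zips <- assert_count(n_zips, "n_zips")
  assert_scalar_number(mean_zip_population, "mean_zip_population",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(sdoh_sd, "sdoh_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(commercial_share_slope, "commercial_share_slope")
  assert_scalar_number(commercial_share_base, "commercial_share_base",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(medicaid_share_of_rest, "medicaid_share_of_rest",
                       lower = 0, upper = 1)

  seeds <- child_seeds(seed, c("sdoh", "population"))
  sdoh <- with_seed(seeds[["sdoh"]], rnorm(n_zips, mean = 0, sd = sdoh_sd))
  pop <- with_seed(seeds[["population"]], {
    pmax(1, round(rlnorm(
      n_zips,
      meanlog = log(mean_zip_population) - population_sdlog^2 / 2,
      sdlog = population_sdlog
    )))
  })

  share_c <- plogis(qlogis(commercial_share_base) - commercial_share_slope * sdoh)
  pop_commercial <- round(pop * share_c)
  rest <- pop - pop_commercial
  pop_medicaid <- round(rest * medicaid_share_of_rest)
  pop_uninsured <- rest - pop_medicaid

  tibble::tibble(
    zip_id = zero_pad_ids("z", n_zips),
    pop_commercial = as.integer(pop_commercial),
    pop_medicaid = as.integer(pop_medicaid),
    pop_uninsured = as.integer(pop_uninsured),
    sdoh = sdoh
  )
}

#' Generate synthetic procedure rate profiles
#'
#' Each procedure k has a log-linear zip-level rate model
#' `log(rate_ik) = log_base_rate_k + sdoh_slope_k * sdoh_i`, in events per
#' person-year, optionally scaled by a per-stratum multiplier. The slope
#' (beta1) measures how strongly the procedure concentrates in deprived
#' areas; it is drawn normal(0, `beta1_sd`). The log base rate (beta0) is
#' uniform on `beta0_range`.
#'
#' @param n_procedures Number of procedures.
#' @param beta0_range Length-2 numeric: range of the log base rate. Must give
#'   rates in (0, 1] events per person-year.
#' @param beta1_sd SD of the SDOH slope draw (> 0; use e.g. 1e-12 for the
#'   no-association limit).
#' @param seed Integer seed.
#' @param stratum_multipliers Named positive multipliers for
#'   commercial/medicaid/uninsured rates (default all 1).
#'
#' @return A tibble with columns `procedure_id`, `log_base_rate`,
#'   `sdoh_slope`, `mult_commercial`, `mult_medicaid`, `mult_uninsured`.
#' @export
generate_procedure_profiles <- function(n_procedures = 250,
                                        beta0_range = log(c(3e-5, 3e-3)),
                                        beta1_sd = 0.5,
                                        seed,
                                        stratum_multipliers = c(
                                          commercial = 1, medicaid = 1,
                                          uninsured = 1
                                        )) {
  n_procedures <- assert_count(n_procedures, "n_procedures")
  if (!is.numeric(beta0_range) || length(beta0_range) != 2L ||
      any(!is.finite(beta0_range)) || beta0_range[1] > beta0_range[2]) {
    abort("`beta0_range` must be a finite numeric interval c(lo, hi), lo <= hi.")
  }
  if (exp(beta0_range[2]) > 1) {
    abort("`beta0_range` implies base rates > 1 event/person-year; not realistic.")
  }
  assert_scalar_number(beta1_sd, "beta1_sd", lower = 0, strict_lower = TRUE)
  if (!all(STRATA %in% names(stratum_multipliers)) ||
      any(stratum_multipliers[STRATA] <= 0)) {
    abort("`stratum_multipliers` must name positive values for commercial, medicaid, uninsured.")
  }

  seeds <- child_seeds(seed, c("beta0", "beta1"))
  beta0 <- with_seed(seeds[["beta0"]],
                     runif(n_procedures, beta0_range[1], beta0_range[2]))
  beta1 <- with_seed(seeds[["beta1"]], rnorm(n_procedures, 0, beta1_sd))

  tibble::tibble(
    procedure_id = zero_pad_ids("proc", n_procedures),
    log_base_rate = beta0,
    sdoh_slope = beta1,
    mult_commercial = unname(stratum_multipliers[["commercial"]]),
    mult_medicaid = unname(stratum_multipliers[["medicaid"]]),
    mult_uninsured = unname(stratum_multipliers[["uninsured"]])
  )
}

#' Define the claims-cohort selection mechanism
#'
#' Members of the commercial stratum are enrolled into the claims cohort with
#' a zip-level probability that depends on the zip's SDOH score:
#' log-linear (`exp(intercept + sdoh_coefficient * sdoh)`) or logistic
#' (`plogis(intercept + sdoh_coefficient * sdoh)`). Because SDOH is oriented
#' deprivation-high, a *negative* `sdoh_coefficient` encodes the empirical
#' pattern that affluent areas are over-sampled into commercial claims data.
#' Enrollees hold partial-year coverage: a point mass of fully covered
#' enrollees (probability `p_full`, 365 days) and a Beta-distributed
#' remainder calibrated so the overall mean coverage fraction equals
#' `coverage_mean_fraction`.
#'
#' @param link `"loglinear"` or `"logistic"`.
#' @param intercept Link-scale intercept.
#' @param sdoh_coefficient Link-scale SDOH coefficient (negative =
#'   deprivation-avoiding selection).
#' @param coverage_mean_fraction Mean fraction of the 365-day year covered,
#'   in (0, 1]. Default 0.832 (mean 303.6 days).
#' @param p_full Probability of full-year (365-day) coverage.
#' @param coverage_shape Beta dispersion (a + b) for the partial-coverage
#'   component.
#'
#' @return An object of class `selection_model`.
#' @export
selection_model <- function(link = c("loglinear", "logistic"),
                            intercept = log(0.094),
                            sdoh_coefficient = -0.5,
                            coverage_mean_fraction = 0.832,
                            p_full = 0.5,
                            coverage_shape = 5) {
  link <- match.arg(link)
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(sdoh_coefficient, "sdoh_coefficient")
  assert_scalar_number(coverage_mean_fraction, "coverage_mean_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(p_full, "p_full", lower = 0, upper = 1)
  assert_scalar_number(coverage_shape, "coverage_shape",
                       lower = 0, strict_lower = TRUE)
  if (coverage_mean_fraction < 1 && p_full >= 1) {
    abort("`p_full` = 1 requires `coverage_mean_fraction` = 1.")
  }
  if (coverage_mean_fraction < 1 &&
      (coverage_mean_fraction - p_full) / (1 - p_full) <= 0) {
    abort("`coverage_mean_fraction` must exceed `p_full` (the full-year point mass alone would overshoot the mean).")
  }
  structure(
    list(
      link = link,
      intercept = intercept,
      sdoh_coefficient = sdoh_coefficient,
      coverage_mean_fraction = coverage_mean_fraction,
      p_full = p_full,
      coverage_shape = coverage_shape
    ),
    class = "selection_model"
  )
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf(
    "<selection_model> link=%s intercept=%.4g sdoh_coefficient=%.4g coverage_mean_fraction=%.3f\n",
    x$link, x$intercept, x$sdoh_coefficient, x$coverage_mean_fraction
  ))
  invisible(x)
}

#' Per-zip inclusion probability under a selection model
#'
#' @param selection A [selection_model()].
#' @param sdoh Numeric vector of zip SDOH scores.
#' @return Numeric vector of probabilities (not clipped; validated by
#'   [simulate_study()]).
#' @export
inclusion_probability <- function(selection, sdoh) {
  stopifnot(inherits(selection, "selection_model"))
  eta <- selection$intercept + selection$sdoh_coefficient * sdoh
  switch(selection$link, loglinear = exp(eta), logistic = plogis(eta))
}

check_selection <- function(selection, zip_areas) {
  p <- inclusion_probability(selection, zip_areas$sdoh)
  bad <- which(p < 0 | p > 1)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Selection probability outside [0, 1] for zip(s): %s (first offending value %.4g).",
      paste(head(zip_areas$zip_id[bad], 5L), collapse = ", "), p[bad[1]]
    ))
  }
  p
}

# Beta parameters for the partial-coverage component, solved from the
# overall mean fraction, the full-year point mass, and a fixed dispersion.
coverage_beta_params <- function(selection) {
  m <- (selection$coverage_mean_fraction - selection$p_full) /
    (1 - selection$p_full)
  list(a = m * selection$coverage_shape, b = (1 - m) * selection$coverage_shape)
}

draw_coverage_days <- function(n, selection) {
  if (n == 0L) return(integer(0))
  if (selection$coverage_mean_fraction >= 1) return(rep(365L, n))
  full <- runif(n) < selection$p_full
  days <- rep(365L, n)
  n_part <- sum(!full)
  if (n_part > 0L) {
    par <- coverage_beta_params(selection)
    days[!full] <- pmin(365L, pmax(1L, as.integer(round(
      365 * rbeta(n_part, par$a, par$b)
    ))))
  }
  days
}

# zips x procedures matrix of per-person-year rates (before stratum
# multipliers): exp(beta0_k + beta1_k * sdoh_i)
rate_matrix <- function(zip_areas, profiles) {
  exp(outer(zip_areas$sdoh, profiles$sdoh_slope) +
        matrix(profiles$log_base_rate, nrow = nrow(zip_areas),
               ncol = nrow(profiles), byrow = TRUE))
}

counts_to_long <- function(counts, zip_ids, procedure_ids) {
  idx <- which(counts > 0L, arr.ind = TRUE)
  tibble::tibble(
    zip_id = zip_ids[idx[, 1L]],
    procedure_id = procedure_ids[idx[, 2L]],
    count = as.integer(counts[idx])
  )
}

#' Simulate a paired reference/claims study
#'
#' Realizes one synthetic study: reference discharge counts are Poisson draws
#' per (zip, stratum, procedure) with mean
#' `pop * exp(beta0 + beta1 * sdoh) * multiplier`; claims enrollment is a
#' binomial thinning of each zip's commercial stratum at the selection
#' model's inclusion probability; each enrollee gets partial-year coverage;
#' and claims discharge counts are Poisson draws with exposure equal to the
#' realized covered person-years in the zip. Counts are drawn at the (zip,
#' stratum) aggregation level -- person identity exists only in the
#' enrollment table.
#'
#' @param zip_areas Tibble from [generate_zip_areas()].
#' @param profiles Tibble from [generate_procedure_profiles()].
#' @param selection A [selection_model()].
#' @param seed Integer seed (per-component child streams keep zip, reference,
#'   enrollment, coverage and claims draws independent).
#'
#' @return An object of class `simulated_study`: a list with elements
#'   `zip_areas`, `reference_discharges` (zip_id, procedure_id, stratum,
#'   count), `claims_enrollment` (enrollee_id, zip_id, coverage_days),
#'   `claims_discharges` (zip_id, procedure_id, count) and `truth`
#'   (the generating profiles and selection model).
#' @export
simulate_study <- function(zip_areas, profiles, selection, seed) {
  assert_columns(zip_areas, c("zip_id", "pop_commercial", "pop_medicaid",
                              "pop_uninsured", "sdoh"), "zip_areas")
  assert_columns(profiles, c("procedure_id", "log_base_rate", "sdoh_slope",
                             "mult_commercial", "mult_medicaid",
                             "mult_uninsured"), "profiles")
  p_incl <- check_selection(selection, zip_areas)
  seeds <- child_seeds(seed, c("reference", "enrollment", "coverage", "claims"))

  n_zip <- nrow(zip_areas)
  n_proc <- nrow(profiles)
  lam <- rate_matrix(zip_areas, profiles)

  reference_discharges <- with_seed(seeds[["reference"]], {
    purrr::map_dfr(STRATA, function(str) {
      pop <- zip_areas[[paste0("pop_", str)]]
      mult <- profiles[[paste0("mult_", str)]]
      # pop recycles down rows, mult across columns
      mu <- pop * lam * rep(mult, each = n_zip)
      counts <- matrix(rpois(length(mu), mu), nrow = n_zip)
      out <- counts_to_long(counts, zip_areas$zip_id, profiles$procedure_id)
      out$stratum <- str
      out
    }) |>
      dplyr::select("zip_id", "procedure_id", "stratum", "count") |>
      dplyr::arrange(.data$zip_id, .data$procedure_id, .data$stratum)
  })

  n_enrolled <- with_seed(seeds[["enrollment"]],
                          rbinom(n_zip, zip_areas$pop_commercial, p_incl))
  claims_enrollment <- tibble::tibble(
    enrollee_id = zero_pad_ids("e", sum(n_enrolled)),
    zip_id = rep(zip_areas$zip_id, n_enrolled)
  )
  claims_enrollment$coverage_days <- with_seed(
    seeds[["coverage"]], draw_coverage_days(nrow(claims_enrollment), selection)
  )

  covered_py <- claims_enrollment |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::summarise(py = sum(.data$coverage_days) / 365, .groups = "drop")
  py_by_zip <- setNames(rep(0, n_zip), zip_areas$zip_id)
  py_by_zip[covered_py$zip_id] <- covered_py$py

  claims_discharges <- with_seed(seeds[["claims"]], {
    mu <- py_by_zip * lam * rep(profiles$mult_commercial, each = n_zip)
    counts <- matrix(rpois(length(mu), mu), nrow = n_zip)
    counts_to_long(counts, zip_areas$zip_id, profiles$procedure_id) |>
      dplyr::arrange(.data$zip_id, .data$procedure_id)
  })

  structure(
    list(
      zip_areas = zip_areas,
      reference_discharges = reference_discharges,
      claims_enrollment = claims_enrollment,
      claims_discharges = claims_discharges,
      truth = list(profiles = profiles, selection = selection)
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d zips, %d procedures, %d enrollees, %d reference / %d claims discharge rows\n",
    nrow(x$zip_areas), nrow(x$truth$profiles), nrow(x$claims_enrollment),
    nrow(x$reference_discharges), nrow(x$claims_discharges)
  ))
  invisible(x)
}

#' Exact expected relative bias under a selection model
#'
#' Analytic (no Monte Carlo) finite-population expectation of the relative
#' bias statistic -- expected claims rate per covered person-year divided by
#' the expected target-population rate per person-year -- by direct summation
#' over zips and strata. Serves as the oracle against which pipeline
#' estimates are checked.
#'
#' @inheritParams simulate_study
#' @param target Target population: `"all"`, `"insured"` (commercial +
#'   medicaid), or `"commercial"`.
#' @return A tibble with columns `procedure_id`, `expected_bias`.
#' @export
expected_relative_bias <- function(zip_areas, profiles, selection,
                                   target = c("all", "insured", "commercial")) {
  target <- match.arg(target)
  assert_columns(zip_areas, c("zip_id", "pop_commercial", "pop_medicaid",
                              "pop_uninsured", "sdoh"), "zip_areas")
  p_incl <- check_selection(selection, zip_areas)
  lam <- rate_matrix(zip_areas, profiles)

  # Claims side: expected covered person-years per zip weight the commercial
  # rates.
  w <- zip_areas$pop_commercial * p_incl * selection$coverage_mean_fraction
  if (sum(w) <= 0) abort("Expected claims exposure is zero; nothing is enrolled.")
  claims_rate <- as.numeric(crossprod(w, lam)) * profiles$mult_commercial / sum(w)

  strata <- target_strata(target)
  pops <- sapply(strata, function(s) zip_areas[[paste0("pop_", s)]],
                 simplify = FALSE)
  total_pop <- sum(unlist(pops))
  if (total_pop <= 0) abort(sprintf("Target population `%s` is empty.", target))
  ref_events <- Reduce(`+`, lapply(strata, function(s) {
    as.numeric(crossprod(pops[[s]], lam)) * profiles[[paste0("mult_", s)]]
  }))
  ref_rate <- ref_events / total_pop

  undefined <- ref_rate <= 0
  if (any(undefined)) {
    abort(sprintf(
      "Expected reference rate is zero for procedure(s): %s; relative bias undefined.",
      paste(head(profiles$procedure_id[undefined], 5L), collapse = ", ")
    ))
  }

  tibble::tibble(
    procedure_id = profiles$procedure_id,
    expected_bias = claims_rate / ref_rate
  )
}
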