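# Small fixture builders shared across test files.

# Uniform (SDOH-independent) selection with full-year coverage by default.
uniform_selection <- function(p = 1, coverage_mean_fraction = 1) {
  selection_model(
    link = "loglinear", intercept = log(p), sdoh_coefficient = 0,
    coverage_mean_fraction = coverage_mean_fraction
  )
}

# Hand-built zip areas: equal-length vectors of stratum populations + sdoh.
toy_zips <- function(pop_commercial, pop_medicaid = 0, pop_uninsured = 0,
                     sdoh = 0) {
  n <- max(length(pop_commercial), length(pop_medicaid),
           length(pop_uninsured), length(sdoh))
  tibble::tibble(
    zip_id = sprintf("z%02d", seq_len(n)),
    pop_commercial = as.integer(rep_len(pop_commercial, n)),
    pop_medicaid = as.integer(rep_len(pop_medicaid, n)),
    pop_uninsured = as.integer(rep_len(pop_uninsured, n)),
    sdoh = rep_len(sdoh, n)
  )
}

# Hand-built procedure profiles.
toy_profiles <- function(log_base_rate, sdoh_slope = 0,
                         mult = c(commercial = 1, medicaid = 1, uninsured = 1)) {
  n <- max(length(log_base_rate), length(sdoh_slope))
  tibble::tibble(
    procedure_id = sprintf("proc%02d", seq_len(n)),
    log_base_rate = rep_len(log_base_rate, n),
    sdoh_slope = rep_len(sdoh_slope, n),
    mult_commercial = mult[["commercial"]],
    mult_medicaid = mult[["medicaid"]],
    mult_uninsured = mult[["uninsured"]]
  )
}

# Independent Poisson log-likelihood for the zip-level offset GLM, used by
# the brute-force grid-search oracle.
poisson_offset_loglik <- function(beta0, beta1, count, pop, score) {
  eta <- beta0 + beta1 * score + log(pop)
  sum(count * eta - exp(eta))
}
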