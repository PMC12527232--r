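test_that("generated zip areas have the advertised SDOH and share structure", {
  z <- generate_zip_areas(n_zips = 400, sdoh_sd = 1, seed = 7)
  expect_equal(nrow(z), 400)
  expect_false(anyDuplicated(z$zip_id) > 0)
  # law-of-large-numbers band: |mean| <= 3/sqrt(n)
  expect_lt(abs(mean(z$sdoh)), 3 / sqrt(400))
  total <- z$pop_commercial + z$pop_medicaid + z$pop_uninsured
  expect_true(all(total >= 1))
  expect_true(all(z$pop_commercial >= 0 & z$pop_medicaid >= 0 &
                    z$pop_uninsured >= 0))

  # slope 0: commercial share is the same logistic constant in every zip
  z0 <- generate_zip_areas(200, commercial_share_slope = 0, seed = 5)
  tot0 <- z0$pop_commercial + z0$pop_medicaid + z0$pop_uninsured
  expect_equal(z0$pop_commercial, as.integer(round(tot0 * 0.72)))

  # commercial share falls with deprivation when the slope is positive
  expect_lt(
    stats::cor(z$sdoh, z$pop_commercial / total), 0
  )
})

test_that("zip-area generation is deterministic and validates arguments", {
  a <- generate_zip_areas(50, seed = 42)
  b <- generate_zip_areas(50, seed = 42)
  expect_identical(a, b)
  expect_error(generate_zip_areas(0, seed = 1), "n_zips")
  expect_error(generate_zip_areas(10, sdoh_sd = 0, seed = 1), "sdoh_sd")
})

test_that("procedure profiles reproduce the requested slope distribution", {
  p <- generate_procedure_profiles(250, beta1_sd = 0.5, seed = 1)
  expect_equal(nrow(p), 250)
  # 3-sigma band for the sd of 250 normal draws
  expect_gt(sd(p$sdoh_slope), 0.35)
  expect_lt(sd(p$sdoh_slope), 0.65)
  expect_true(all(exp(p$log_base_rate) > 0 & exp(p$log_base_rate) <= 1))

  degenerate <- generate_procedure_profiles(20, beta1_sd = 1e-12, seed = 2)
  expect_true(all(abs(degenerate$sdoh_slope) < 1e-10))

  expect_identical(generate_procedure_profiles(10, seed = 3),
                   generate_procedure_profiles(10, seed = 3))
  expect_error(
    generate_procedure_profiles(5, beta0_range = c(1, 0), seed = 1),
    "beta0_range"
  )
  expect_error(
    generate_procedure_profiles(5, beta0_range = log(c(0.5, 2)), seed = 1),
    "beta0_range"
  )
})

test_that("uniform selection with unit multipliers is unbiased for every target", {
  # SDOH-independent strata shares: the only sampling channel left is the
  # uniform thinning, which cannot tilt any rate
  z <- generate_zip_areas(100, commercial_share_slope = 0, seed = 21)
  p <- generate_procedure_profiles(8, seed = 22)
  sel <- uniform_selection(p = 0.4, coverage_mean_fraction = 0.8)
  # integer rounding of stratum populations perturbs the shares at O(1/pop)
  for (tg in c("all", "insured", "commercial")) {
    eb <- expected_relative_bias(z, p, sel, target = tg)
    expect_equal(eb$expected_bias, rep(1, 8), tolerance = 1e-4)
  }
})

test_that("expected bias matches weighted-average arithmetic on fixed strata", {
  # shares 0.7 commercial / 0.3 other, multipliers 0.7 vs 1.7:
  # claims rate = 0.7 lambda, reference = (0.7*0.7 + 0.3*1.7) lambda = lambda
  z <- toy_zips(pop_commercial = rep(700, 4), pop_medicaid = 150,
                pop_uninsured = 150, sdoh = c(-1, 0, 1, 2))
  p <- toy_profiles(log_base_rate = log(c(0.001, 0.01)), sdoh_slope = c(0, 0.5),
                    mult = c(commercial = 0.7, medicaid = 1.7, uninsured = 1.7))
  eb <- expected_relative_bias(z, p, uniform_selection(), target = "all")
  expect_equal(eb$expected_bias, c(0.7, 0.7), tolerance = 1e-12)
})

test_that("expected bias matches the two-zip hand computation", {
  # pops 1000/1000 all commercial, inclusion 1.0/0.5, rates 0.01/0.02:
  # claims (1000*.01 + 500*.02)/1500 = 0.01333..; reference 0.015 -> 8/9
  z <- toy_zips(pop_commercial = c(1000, 1000), sdoh = c(0, 1))
  p <- toy_profiles(log_base_rate = log(0.01), sdoh_slope = log(2))
  sel <- selection_model("loglinear", intercept = 0,
                         sdoh_coefficient = log(0.5),
                         coverage_mean_fraction = 1)
  eb <- expected_relative_bias(z, p, sel, target = "all")
  expect_equal(eb$expected_bias, 8 / 9, tolerance = 1e-12)
})

test_that("log expected bias follows the Gaussian MGF identity at many zips", {
  # log-linear selection exp(d*s), rates exp(beta*s), s ~ N(0, sigma^2):
  # E[e^((d+b)s)] / (E[e^(ds)] E[e^(bs)]) = e^(d*b*sigma^2), so the ratio of
  # biases for beta = 0.5 vs beta = 0 tends to e^(-1) when d = -1, sigma^2 = 2
  z <- generate_zip_areas(5000, sdoh_sd = sqrt(2), commercial_share_slope = 0,
                          seed = 11)
  p <- toy_profiles(log_base_rate = log(1e-3), sdoh_slope = c(0.5, 0))
  sel <- selection_model("loglinear", intercept = -6, sdoh_coefficient = -1,
                         coverage_mean_fraction = 1)
  eb <- expected_relative_bias(z, p, sel, target = "all")
  ratio <- eb$expected_bias[1] / eb$expected_bias[2]
  expect_equal(ratio, exp(-1), tolerance = 0.02)
})

test_that("realized claims counts agree with the analytic oracle at large exposure", {
  z <- toy_zips(pop_commercial = rep(10000L, 150),
                sdoh = withr::with_seed(31, rnorm(150)))
  p <- toy_profiles(log_base_rate = log(c(1e-4, 5e-4, 1e-3)),
                    sdoh_slope = c(0.3, -0.2, 0))
  sel <- uniform_selection(p = 0.8)
  st <- simulate_study(z, p, sel, seed = 77)

  py <- compute_person_years(st$claims_enrollment)$person_years
  expect_gt(py, 1e6)
  ref_rate <- expected_reference_rate <- sapply(seq_len(3), function(k) {
    sum(z$pop_commercial * exp(p$log_base_rate[k] + p$sdoh_slope[k] * z$sdoh)) /
      sum(z$pop_commercial)
  })
  eb <- expected_relative_bias(z, p, sel, target = "all")
  observed <- claimsbias:::claims_counts(st, p$procedure_id)$count
  expected <- eb$expected_bias * ref_rate * py
  expect_true(all(abs(observed - expected) <= 4 * sqrt(expected)))
})

test_that("restricting the target toward the claims frame raises the bias", {
  z <- generate_zip_areas(80, seed = 13)
  p <- generate_procedure_profiles(
    6, seed = 14,
    stratum_multipliers = c(commercial = 0.7, medicaid = 1, uninsured = 1)
  )
  sel <- uniform_selection(p = 0.5)
  b_all <- expected_relative_bias(z, p, sel, "all")$expected_bias
  b_com <- expected_relative_bias(z, p, sel, "commercial")$expected_bias
  expect_true(all(b_com > b_all))
  expect_equal(b_com, rep(1, 6), tolerance = 1e-12)
})

test_that("simulated studies are deterministic in the seed and well-formed", {
  z <- generate_zip_areas(30, seed = 1)
  p <- generate_procedure_profiles(4, seed = 2)
  sel <- selection_model()
  a <- simulate_study(z, p, sel, seed = 10)
  b <- simulate_study(z, p, sel, seed = 10)
  expect_identical(a$reference_discharges, b$reference_discharges)
  expect_identical(a$claims_enrollment, b$claims_enrollment)
  expect_identical(a$claims_discharges, b$claims_discharges)

  expect_true(all(a$claims_enrollment$coverage_days >= 1 &
                    a$claims_enrollment$coverage_days <= 365))
  expect_true(all(a$reference_discharges$zip_id %in% z$zip_id))
  expect_true(all(a$claims_discharges$zip_id %in%
                    a$claims_enrollment$zip_id))
})

test_that("selection probabilities outside [0, 1] are rejected with the zip named", {
  z <- toy_zips(pop_commercial = c(100, 100), sdoh = c(0, 2))
  p <- toy_profiles(log_base_rate = log(0.01))
  sel <- selection_model("loglinear", intercept = 0, sdoh_coefficient = 0.5,
                         coverage_mean_fraction = 1)
  expect_error(simulate_study(z, p, sel, seed = 1), "z02")
  expect_error(expected_relative_bias(z, p, sel), "z02")
})
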