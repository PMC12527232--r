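test_that("tract scores roll up to zips by population weighting", {
  tracts <- tibble::tibble(
    tract_id = c("t1", "t2", "t3", "t4", "t5"),
    zip_id = c("z1", "z1", "z2", "z3", "z3"),
    population = c(100, 300, 500, 0, 0),
    value = c(1, 2, 7, 3, 4)
  )
  m <- aggregate_tract_to_zip(tracts)
  expect_equal(m$score[m$zip_id == "z1"], 1.75) # (100*1 + 300*2) / 400
  expect_equal(m$score[m$zip_id == "z2"], 7)    # single tract
  expect_true(is.na(m$score[m$zip_id == "z3"])) # zero population -> missing
  expect_equal(attr(m, "orientation"), "deprivation_high")

  equal_vals <- tibble::tibble(tract_id = c("a", "b"), zip_id = "z",
                               population = c(10, 990), value = 5)
  expect_equal(aggregate_tract_to_zip(equal_vals)$score, 5)
})

test_that("PCA SES score is the signed first principal component", {
  ind <- withr::with_seed(8, tibble::tibble(
    zip_id = sprintf("z%02d", 1:40),
    income = rnorm(40, 60, 10),
    college = rnorm(40, 0.3, 0.05),
    noise = rnorm(40)
  ))
  m <- pca_ses(ind, advantage_col = "income")
  expect_equal(mean(m$score), 0, tolerance = 1e-12)
  expect_gt(stats::cor(m$score, ind$income), 0)
  expect_equal(attr(m, "orientation"), "advantage_high")

  # variance of the score equals the leading eigenvalue of the correlation
  # matrix (eigen-decomposition oracle; prcomp divides by n - 1)
  lead_eig <- max(eigen(stats::cor(ind[-1]), symmetric = TRUE)$values)
  expect_equal(var(m$score), lead_eig, tolerance = 1e-10)

  # single indicator: score is the standardized column (up to the sign rule)
  single <- pca_ses(ind[c("zip_id", "income")])
  expect_equal(single$score, as.numeric(scale(ind$income)), tolerance = 1e-10)

  # two identical columns: first component carries all the variance
  dup <- tibble::tibble(zip_id = ind$zip_id, a = ind$income, b = ind$income)
  expect_equal(attr(pca_ses(dup), "var_explained"), 1, tolerance = 1e-10)

  # sign rule is deterministic
  expect_identical(pca_ses(ind, "income")$score, pca_ses(ind, "income")$score)

  expect_error(pca_ses(dplyr::mutate(ind, flat = 1)), "flat")
})

test_that("a two-point saturated fit recovers the closed-form slope", {
  # empirical rates 0.01 at s = 0 and 0.02 at s = 1 -> beta1 = ln 2 exactly
  counts <- tibble::tibble(
    zip_id = c("a", "b"), count = c(10L, 20L), population = c(1000, 1000)
  )
  metric <- sdoh_metric(tibble::tibble(zip_id = c("a", "b"), score = c(0, 1)))
  fit <- fit_sdoh_poisson(counts, metric)
  expect_true(fit$converged)
  expect_equal(fit$beta1, log(2), tolerance = 1e-8)
  expect_equal(fit$beta0, log(0.01), tolerance = 1e-8)
})

test_that("the offset GLM recovers a known slope from simulated counts", {
  n <- 2000
  df <- withr::with_seed(41, {
    score <- rnorm(n)
    pop <- rep(3000, n)
    tibble::tibble(
      zip_id = sprintf("z%04d", 1:n),
      population = pop,
      score = score,
      count = rpois(n, pop * exp(log(2e-3) - 0.8 * score))
    )
  })
  fit <- fit_sdoh_poisson(df[c("zip_id", "count", "population")],
                          df[c("zip_id", "score")])
  expect_lt(abs(fit$beta1 - (-0.8)), 3 * fit$se_beta1)

  # constant rate: slope consistent with 0
  df0 <- withr::with_seed(42, dplyr::mutate(
    df, count = rpois(n, .data$population * 2e-3)
  ))
  fit0 <- fit_sdoh_poisson(df0[c("zip_id", "count", "population")],
                           df0[c("zip_id", "score")])
  expect_lt(abs(fit0$beta1), 3 * fit0$se_beta1)
})

test_that("offset handling and affine equivariance hold exactly", {
  counts <- tibble::tibble(
    zip_id = sprintf("z%02d", 1:30),
    count = withr::with_seed(3, rpois(30, 15)),
    population = seq(500, 3400, by = 100)
  )
  metric <- sdoh_metric(tibble::tibble(
    zip_id = counts$zip_id, score = seq(-1.5, 1.4, by = 0.1)
  ))
  base <- fit_sdoh_poisson(counts, metric)

  doubled <- fit_sdoh_poisson(
    dplyr::mutate(counts, population = 2 * .data$population), metric
  )
  expect_equal(doubled$beta1, base$beta1, tolerance = 1e-8)
  expect_equal(doubled$beta0, base$beta0 - log(2), tolerance = 1e-8)

  a <- 2.5
  b <- -0.7
  rescaled <- fit_sdoh_poisson(
    counts,
    sdoh_metric(tibble::tibble(zip_id = metric$zip_id,
                               score = a * metric$score + b))
  )
  expect_equal(rescaled$beta1, base$beta1 / a, tolerance = 1e-8)
  # fitted means unchanged under the affine map
  expect_equal(rescaled$beta0 + rescaled$beta1 * (a * metric$score + b),
               base$beta0 + base$beta1 * metric$score, tolerance = 1e-7)
})

test_that("the GLM matches a brute-force likelihood grid search", {
  counts <- tibble::tibble(
    zip_id = c("a", "b", "c"), count = c(4L, 9L, 20L),
    population = c(800, 1000, 1200)
  )
  metric <- sdoh_metric(tibble::tibble(zip_id = c("a", "b", "c"),
                                       score = c(-1, 0, 1)))
  fit <- fit_sdoh_poisson(counts, metric)

  # nested grid refinement around the likelihood maximum
  b0 <- seq(-8, -2, length.out = 61)
  b1 <- seq(-2, 2, length.out = 61)
  for (level in 1:4) {
    ll <- outer(b0, b1, Vectorize(function(x, y) {
      poisson_offset_loglik(x, y, counts$count, counts$population,
                            metric$score)
    }))
    best <- arrayInd(which.max(ll), dim(ll))
    step0 <- b0[2] - b0[1]
    step1 <- b1[2] - b1[1]
    center0 <- b0[best[1]]
    center1 <- b1[best[2]]
    b0 <- seq(center0 - step0, center0 + step0, length.out = 41)
    b1 <- seq(center1 - step1, center1 + step1, length.out = 41)
  }
  expect_equal(fit$beta0, center0, tolerance = 1e-4)
  expect_equal(fit$beta1, center1, tolerance = 1e-4)
})

test_that("degenerate inputs are flagged, not fitted", {
  metric <- sdoh_metric(tibble::tibble(zip_id = c("a", "b"), score = c(0, 1)))
  zero <- fit_sdoh_poisson(
    tibble::tibble(zip_id = c("a", "b"), count = 0L, population = 100),
    metric
  )
  expect_false(zero$identifiable)
  expect_true(is.na(zero$beta1))

  flat <- fit_sdoh_poisson(
    tibble::tibble(zip_id = c("a", "b"), count = c(3L, 5L), population = 100),
    sdoh_metric(tibble::tibble(zip_id = c("a", "b"), score = c(1, 1)))
  )
  expect_false(flat$identifiable)

  # zero-population and missing-score zips are dropped, and counted
  part <- fit_sdoh_poisson(
    tibble::tibble(zip_id = c("a", "b", "c", "d"),
                   count = c(3L, 5L, 2L, 7L),
                   population = c(100, 100, 0, 100)),
    sdoh_metric(tibble::tibble(zip_id = c("a", "b", "c", "d"),
                               score = c(0, 1, 2, NA)))
  )
  expect_equal(part$n_zips_used, 2L)
})

test_that("fit_sdoh_slopes completes absent zip/procedure pairs with zeros", {
  z <- generate_zip_areas(60, seed = 6)
  p <- toy_profiles(log_base_rate = log(c(5e-4, 1e-3)), sdoh_slope = c(0.4, 0))
  st <- simulate_study(z, p, uniform_selection(0.5), seed = 8)
  metric <- sdoh_metric(tibble::tibble(zip_id = z$zip_id, score = z$sdoh))
  pops <- tibble::tibble(
    zip_id = z$zip_id,
    population = z$pop_commercial + z$pop_medicaid + z$pop_uninsured
  )
  slopes <- fit_sdoh_slopes(zip_procedure_counts(st), metric,
                            populations = pops)
  expect_equal(nrow(slopes), 2)
  expect_equal(slopes$n_zips_used, c(60L, 60L))
  expect_true(all(slopes$converged))

  one <- fit_sdoh_poisson(
    dplyr::filter(zip_procedure_counts(st), procedure_id == "proc01"),
    metric
  )
  expect_s3_class(tidy(one), "tbl_df")
  expect_equal(glance(one)$beta1, one$beta1)
})
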