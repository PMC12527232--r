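#' Construct a zip-level SDOH metric table
#'
#' A thin wrapper that validates and tags a (zip_id, score) table with the
#' metric's name and orientation. Orientation matters downstream: with
#' `deprivation_high` (the NDI convention) a *negative* meta-regression
#' slope means procedures concentrated in deprived areas are underestimated.
#'
#' @param scores Tibble with columns `zip_id`, `score` (NA = explicitly
#'   missing).
#' @param name Metric name, e.g. `"ndi"`, `"pca_ses"`, `"custom"`.
#' @param orientation `"deprivation_high"` or `"advantage_high"`.
#' @return The tibble, classed `sdoh_metric`, with attributes `metric_name`
#'   and `orientation`.
#' @export
sdoh_metric <- function(scores, name = "custom",
                        orientation = c("deprivation_high", "advantage_high")) {
  orientation <- match.arg(orientation)
  assert_columns(scores, c("zip_id", "score"), "scores")
  if (anyDuplicated(scores$zip_id)) abort("`zip_id` must be unique.")
  structure(
    tibble::as_tibble(scores[c("zip_id", "score")]),
    metric_name = name,
    orientation = orientation,
    class = c("sdoh_metric", class(tibble::tibble()))
  )
}

#' Aggregate a tract-level deprivation score to zip level
#'
#' Population-weighted average of the tract values within each zip:
#' `sum(pop_t * value_t) / sum(pop_t)`. Zips whose tracts all have zero
#' population get an explicit missing score (NA) rather than an error.
#'
#' @param tracts Tibble with columns `tract_id`, `zip_id`, `population`,
#'   `value`.
#' @param name Metric name recorded on the result.
#' @param orientation Score orientation (NDI is deprivation-high).
#' @return An [sdoh_metric()] tibble (zip_id, score).
#' @export
aggregate_tract_to_zip <- function(tracts, name = "ndi",
                                   orientation = "deprivation_high") {
  assert_columns(tracts, c("tract_id", "zip_id", "population", "value"),
                 "tracts")
  if (any(tracts$population < 0)) abort("Tract populations must be >= 0.")
  out <- tracts |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::summarise(
      score = if (sum(.data$population) > 0) {
        sum(.data$population * .data$value) / sum(.data$population)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  sdoh_metric(out, name = name, orientation = orientation)
}

#' PCA-based socioeconomic status index
#'
#' Standardizes each indicator column (mean 0, sd 1) and takes the first
#' principal component as a single socioeconomic score. The component's sign
#' is fixed deterministically so the score correlates positively with a
#' caller-designated "advantage" indicator (e.g. median income), giving an
#' advantage-high orientation.
#'
#' @param indicators Tibble: `zip_id` plus numeric indicator columns (no
#'   missing cells; imputation is out of scope).
#' @param advantage_col Name of the indicator column that defines the
#'   positive direction; defaults to the first indicator.
#' @return An [sdoh_metric()] tibble with attributes `metric_name =
#'   "pca_ses"`, `orientation = "advantage_high"`, and `var_explained` (the
#'   leading eigenvalue's share of total variance).
#' @export
pca_ses <- function(indicators, advantage_col = NULL) {
  assert_columns(indicators, "zip_id", "indicators")
  mat <- as.data.frame(indicators[setdiff(names(indicators), "zip_id")])
  if (nrow(mat) < 2L || ncol(mat) < 1L) {
    abort("Need at least 2 zips and 1 indicator column.")
  }
  if (anyNA(mat)) abort("Missing indicator cells are not supported.")
  sds <- vapply(mat, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("Constant indicator column(s): %s.",
                  paste(names(mat)[sds == 0], collapse = ", ")))
  }
  if (is.null(advantage_col)) advantage_col <- names(mat)[1L]
  if (!advantage_col %in% names(mat)) {
    abort(sprintf("`advantage_col` '%s' is not an indicator column.",
                  advantage_col))
  }

  pc <- prcomp(mat, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1L]
  # deterministic sign: positive correlation with the advantage indicator
  if (stats::cor(score, mat[[advantage_col]]) < 0) score <- -score

  out <- sdoh_metric(
    tibble::tibble(zip_id = indicators$zip_id, score = unname(score)),
    name = "pca_ses", orientation = "advantage_high"
  )
  attr(out, "var_explained") <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  out
}

#' Zip-level Poisson regression of procedure counts on an SDOH metric
#'
#' Fits, for one procedure, `log(E[count_i] / pop_i) = beta0 + beta1 *
#' sdoh_i` by Poisson maximum likelihood with a log link and offset
#' `log(pop_i)` (IRLS, relative tolerance 1e-10, up to 100 iterations;
#' standard errors from the observed information). `beta1` measures how
#' strongly the procedure concentrates in zips with high values of the
#' metric. Zips with zero population or a missing score are dropped and
#' reflected in `n_zips_used`.
#'
#' @param counts Tibble with columns `zip_id`, `count`, `population`, one
#'   row per zip, for a single procedure.
#' @param metric An [sdoh_metric()] (or any zip_id/score tibble).
#' @param procedure_id Label stored on the fit.
#' @return An object of class `sdoh_fit`: list with `procedure_id`, `beta0`,
#'   `beta1`, `se_beta0`, `se_beta1`, `converged`, `identifiable`,
#'   `n_zips_used`. [tidy()] and [glance()] methods are provided.
#' @export
fit_sdoh_poisson <- function(counts, metric, procedure_id = NULL) {
  assert_columns(counts, c("zip_id", "count", "population"), "counts")
  assert_columns(metric, c("zip_id", "score"), "metric")
  if (is.null(procedure_id)) {
    procedure_id <- if ("procedure_id" %in% names(counts)) {
      as.character(counts$procedure_id[1L])
    } else {
      "procedure"
    }
  }

  df <- dplyr::inner_join(
    counts[c("zip_id", "count", "population")],
    metric[c("zip_id", "score")],
    by = "zip_id"
  ) |>
    dplyr::filter(.data$population > 0, !is.na(.data$score))

  res <- list(
    procedure_id = procedure_id, beta0 = NA_real_, beta1 = NA_real_,
    se_beta0 = NA_real_, se_beta1 = NA_real_, converged = FALSE,
    identifiable = FALSE, n_zips_used = nrow(df)
  )
  if (dplyr::n_distinct(df$score) < 2L || all(df$count == 0)) {
    return(structure(res, class = "sdoh_fit"))
  }

  fit <- suppressWarnings(glm(
    count ~ score,
    family = poisson(link = "log"),
    data = df,
    offset = log(df$population),
    control = glm.control(epsilon = 1e-10, maxit = 100)
  ))
  se <- sqrt(diag(vcov(fit)))
  res$beta0 <- unname(coef(fit)[1L])
  res$beta1 <- unname(coef(fit)[2L])
  res$se_beta0 <- unname(se[1L])
  res$se_beta1 <- unname(se[2L])
  res$converged <- isTRUE(fit$converged)
  res$identifiable <- TRUE
  if (!res$converged) {
    warn(sprintf("non_converged_fit procedure_id=%s", procedure_id))
  }
  structure(res, class = "sdoh_fit")
}

#' @export
print.sdoh_fit <- function(x, ...) {
  cat(sprintf(
    "<sdoh_fit> %s: beta1 = %.4g (SE %.3g), beta0 = %.4g, %d zips%s\n",
    x$procedure_id, x$beta1, x$se_beta1, x$beta0, x$n_zips_used,
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

#' @export
#' @method tidy sdoh_fit
tidy.sdoh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "sdoh"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$se_beta0, x$se_beta1)
  )
}

#' @export
#' @method glance sdoh_fit
glance.sdoh_fit <- function(x, ...) {
  tibble::tibble(
    procedure_id = x$procedure_id,
    beta0 = x$beta0,
    beta1 = x$beta1,
    se_beta1 = x$se_beta1,
    converged = x$converged,
    identifiable = x$identifiable,
    n_zips_used = x$n_zips_used
  )
}

#' Fit the SDOH Poisson regression for every procedure
#'
#' Maps [fit_sdoh_poisson()] over procedures and binds one row per fit.
#'
#' @param counts Tibble with columns `zip_id`, `procedure_id`, `count`,
#'   `population`. Zip/procedure pairs absent from the table are treated as
#'   zero counts (every zip in `metric` contributes to every fit).
#' @param metric An [sdoh_metric()].
#' @param populations Optional tibble (zip_id, population) used to complete
#'   missing zip/procedure pairs with zero counts; defaults to the distinct
#'   zips present in `counts`. Pass the full zip table when a zip may have
#'   no discharges at all, or its denominator would be dropped from every
#'   fit.
#' @return A tibble: `procedure_id`, `beta0`, `beta1`, `se_beta1`,
#'   `converged`, `identifiable`, `n_zips_used`.
#' @export
fit_sdoh_slopes <- function(counts, metric, populations = NULL) {
  assert_columns(counts, c("zip_id", "procedure_id", "count", "population"),
                 "counts")
  if (is.null(populations)) {
    populations <- dplyr::distinct(counts, .data$zip_id, .data$population)
  }
  assert_columns(populations, c("zip_id", "population"), "populations")

  split_counts <- split(
    counts[c("zip_id", "count")],
    counts$procedure_id
  )
  purrr::map_dfr(names(split_counts), function(pid) {
    full <- dplyr::left_join(populations, split_counts[[pid]], by = "zip_id") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
    glance(fit_sdoh_poisson(full, metric, procedure_id = pid))
  }) |>
    dplyr::arrange(.data$procedure_id)
}

#' Per-zip, per-procedure reference counts with populations
#'
#' Convenience reshaper: totals a study's reference discharges over strata
#' and attaches each zip's total population, the input expected by
#' [fit_sdoh_slopes()].
#'
#' @param study A `simulated_study` (or a list with `reference_discharges`
#'   and `zip_areas` of the same schema).
#' @return Tibble: `zip_id`, `procedure_id`, `count`, `population`.
#' @export
zip_procedure_counts <- function(study) {
  pops <- study$zip_areas |>
    dplyr::mutate(population = .data$pop_commercial + .data$pop_medicaid +
                    .data$pop_uninsured) |>
    dplyr::select("zip_id", "population")
  study$reference_discharges |>
    dplyr::group_by(.data$zip_id, .data$procedure_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::inner_join(pops, by = "zip_id")
}
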