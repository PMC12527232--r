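#' Study configuration for the end-to-end pipeline
#'
#' Collects every knob of the synthetic study and the analysis in one
#' validated list. Defaults mirror the reference setting the package
#' emulates: 250 procedures, three target populations, bias-band factors
#' 1.5 and 2.
#'
#' @param seed Root integer seed (child streams are derived per component).
#' @param n_zips,mean_zip_population,sdoh_sd,commercial_share_slope
#'   Passed to [generate_zip_areas()].
#' @param n_procedures,beta0_range,beta1_sd,stratum_multipliers Passed to
#'   [generate_procedure_profiles()].
#' @param selection A [selection_model()].
#' @param targets Target populations to analyze.
#' @param factors Bias-band thresholds (> 1).
#' @param weights Use inverse-variance weights in the meta-regression.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_zips = 1000,
                         mean_zip_population = 8000,
                         sdoh_sd = 1,
                         commercial_share_slope = 1,
                         n_procedures = 250,
                         beta0_range = log(c(3e-5, 3e-3)),
                         beta1_sd = 0.5,
                         stratum_multipliers = c(commercial = 1, medicaid = 1,
                                                 uninsured = 1),
                         selection = selection_model(),
                         targets = c("all", "insured", "commercial"),
                         factors = c(1.5, 2),
                         weights = FALSE,
                         out_dir = NULL) {
  targets <- match.arg(targets, TARGETS, several.ok = TRUE)
  if (any(factors <= 1)) abort("`factors` must all be > 1.")
  stopifnot(inherits(selection, "selection_model"))
  structure(
    list(
      seed = assert_count(seed, "seed", min = 0L),
      n_zips = assert_count(n_zips, "n_zips"),
      mean_zip_population = mean_zip_population,
      sdoh_sd = sdoh_sd,
      commercial_share_slope = commercial_share_slope,
      n_procedures = assert_count(n_procedures, "n_procedures"),
      beta0_range = beta0_range,
      beta1_sd = beta1_sd,
      stratum_multipliers = stratum_multipliers,
      selection = selection,
      targets = targets,
      factors = factors,
      weights = isTRUE(weights),
      out_dir = out_dir
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys map to [study_config()] arguments; the `selection` key is
#' a mapping passed to [selection_model()].
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$selection)) {
    cfg$selection <- do.call(selection_model, cfg$selection)
  }
  if (!is.null(cfg$stratum_multipliers)) {
    cfg$stratum_multipliers <- unlist(cfg$stratum_multipliers)
  }
  if (!is.null(cfg$beta0_range)) cfg$beta0_range <- as.numeric(cfg$beta0_range)
  do.call(study_config, cfg)
}

# Per-procedure claims counts, completed with explicit zeros for every
# procedure in `procedure_ids`.
claims_counts <- function(study, procedure_ids = NULL) {
  if (is.null(procedure_ids)) {
    procedure_ids <- study$truth$profiles$procedure_id
  }
  study$claims_discharges |>
    dplyr::group_by(.data$procedure_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(procedure_id = procedure_ids),
                      by = "procedure_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$procedure_id)
}

#' Estimate per-procedure relative bias from a simulated study
#'
#' Runs the full first stage for one target population: claims person-years
#' from the enrollment table, reference exposure from the (restricted)
#' census populations, per-procedure rates with exact Poisson intervals on
#' both sides, and the claims/reference ratio with a delta-method interval.
#'
#' @param study A `simulated_study` (or list of the same shape).
#' @param target Target population.
#' @param conf_level Confidence level.
#' @return A [relative_bias()] tibble.
#' @export
study_relative_bias <- function(study, target = "all", conf_level = 0.95) {
  ids <- study$truth$profiles$procedure_id
  claims_exposure <- compute_person_years(study$claims_enrollment)
  claims <- estimate_rates(claims_counts(study, ids), claims_exposure,
                           conf_level)

  ref <- restrict_population(study$reference_discharges, study$zip_areas,
                             target)
  ref_counts <- ref$counts |>
    dplyr::right_join(tibble::tibble(procedure_id = ids),
                      by = "procedure_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$procedure_id)
  reference <- estimate_rates(ref_counts, ref$exposure, conf_level)

  relative_bias(claims, reference, conf_level)
}

#' Run the full bias-quantification pipeline
#'
#' simulate -> rates -> relative bias -> SDOH slopes -> meta-regression, for
#' every configured target population, writing each stage's table to
#' `config$out_dir` (if set) and returning a manifest. Reruns with the same
#' config are byte-identical.
#'
#' Written files: `zip_areas.csv`, `reference_discharges.csv`,
#' `claims_enrollment.csv`, `claims_discharges.csv`, `truth.json`,
#' `rates.csv`, `bias.csv`, `slopes.csv`, `meta.csv`, `scatter.csv`,
#' `summary.json`, `manifest.json`.
#'
#' @param config A [study_config()] (or YAML path).
#' @return Invisibly, a list: `study`, `bias` (per target), `slopes`,
#'   `fits` (per target), `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  seeds <- child_seeds(config$seed, c("zips", "profiles", "study"))

  zips <- generate_zip_areas(
    n_zips = config$n_zips,
    mean_zip_population = config$mean_zip_population,
    sdoh_sd = config$sdoh_sd,
    commercial_share_slope = config$commercial_share_slope,
    seed = seeds[["zips"]]
  )
  profiles <- generate_procedure_profiles(
    n_procedures = config$n_procedures,
    beta0_range = config$beta0_range,
    beta1_sd = config$beta1_sd,
    seed = seeds[["profiles"]],
    stratum_multipliers = config$stratum_multipliers
  )
  study <- simulate_study(zips, profiles, config$selection,
                          seed = seeds[["study"]])

  metric <- sdoh_metric(
    tibble::tibble(zip_id = zips$zip_id, score = zips$sdoh),
    name = "ndi", orientation = "deprivation_high"
  )
  slopes <- fit_sdoh_slopes(
    zip_procedure_counts(study), metric,
    populations = tibble::tibble(
      zip_id = zips$zip_id,
      population = zips$pop_commercial + zips$pop_medicaid +
        zips$pop_uninsured
    )
  )

  bias <- lapply(config$targets, function(tg) study_relative_bias(study, tg))
  names(bias) <- config$targets
  summaries <- lapply(bias, bias_summary, factors = config$factors)
  fits <- lapply(config$targets, function(tg) {
    pts <- dplyr::inner_join(
      slopes |>
        dplyr::filter(.data$converged) |>
        dplyr::select("procedure_id", "beta1"),
      bias[[tg]],
      by = "procedure_id"
    )
    fit_loglinear(pts, weights = config$weights, target = tg)
  })
  names(fits) <- config$targets
  comparison <- compare_targets(fits, summaries)

  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("claimsbias")),
    targets = config$targets,
    rows = list(
      zip_areas = nrow(zips),
      reference_discharges = nrow(study$reference_discharges),
      claims_enrollment = nrow(study$claims_enrollment),
      claims_discharges = nrow(study$claims_discharges),
      slopes = nrow(slopes)
    )
  )

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(config, study, slopes, bias, summaries, fits,
                           comparison, manifest)
  }

  invisible(list(
    study = study, bias = bias, summaries = summaries, slopes = slopes,
    fits = fits, comparison = comparison, manifest = manifest
  ))
}

write_pipeline_outputs <- function(config, study, slopes, bias, summaries,
                                   fits, comparison, manifest) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) readr::write_csv(x, file.path(dir, f))

  wcsv(study$zip_areas, "zip_areas.csv")
  wcsv(study$reference_discharges, "reference_discharges.csv")
  wcsv(study$claims_enrollment, "claims_enrollment.csv")
  wcsv(study$claims_discharges, "claims_discharges.csv")
  jsonlite::write_json(
    list(
      profiles = study$truth$profiles,
      selection = unclass(study$truth$selection)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  claims_exposure <- compute_person_years(study$claims_enrollment)
  rates <- purrr::map_dfr(config$targets, function(tg) {
    ref <- restrict_population(study$reference_discharges, study$zip_areas, tg)
    ids <- study$truth$profiles$procedure_id
    ref_counts <- ref$counts |>
      dplyr::right_join(tibble::tibble(procedure_id = ids),
                        by = "procedure_id") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
    dplyr::bind_rows(
      estimate_rates(claims_counts(study, ids), claims_exposure) |>
        dplyr::mutate(cohort = "claims", target = tg),
      estimate_rates(ref_counts, ref$exposure) |>
        dplyr::mutate(cohort = "reference", target = tg)
    )
  }) |>
    dplyr::mutate(
      rate_per_100py = 100 * .data$rate,
      ci_low = 100 * .data$ci_low,
      ci_high = 100 * .data$ci_high
    ) |>
    dplyr::select("cohort", "target", "procedure_id", "count", "person_years",
                  "rate_per_100py", "ci_low", "ci_high")
  wcsv(rates, "rates.csv")

  wcsv(
    purrr::imap_dfr(bias, ~ dplyr::mutate(.x, target = .y)),
    "bias.csv"
  )
  wcsv(slopes, "slopes.csv")
  wcsv(comparison, "meta.csv")
  wcsv(
    purrr::imap_dfr(fits, ~ dplyr::mutate(.x$data, target = .y)),
    "scatter.csv"
  )
  jsonlite::write_json(
    lapply(summaries, function(s) {
      list(
        factors = s$fractions$factor,
        fractions_beyond = s$fractions$fraction_beyond,
        iqr = unname(s$iqr),
        n_procedures = s$n_procedures
      )
    }),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Validate a directory of pipeline input tables
#'
#' Report-only schema, range and referential-integrity checks on the CSV
#' files of a simulated (or externally supplied) study directory. Never
#' raises on data problems: every violation becomes a row.
#'
#' @param dir Directory holding `zip_areas.csv`, `reference_discharges.csv`,
#'   `claims_enrollment.csv`, `claims_discharges.csv` (missing files are
#'   themselves violations).
#' @return A tibble with columns `file`, `row`, `rule`, `message`; zero rows
#'   means a clean directory.
#' @export
validate_inputs <- function(dir) {
  violations <- list()
  note <- function(file, row, rule, message) {
    violations[[length(violations) + 1L]] <<-
      tibble::tibble(file = file, row = row, rule = rule, message = message)
  }
  read <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      note(file, NA_integer_, "file_exists", "file is missing")
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- function(df, file, cols) {
    miss <- setdiff(cols, names(df))
    for (m in miss) note(file, NA_integer_, "schema", paste("missing column", m))
    length(miss) == 0L
  }

  zips <- read("zip_areas.csv")
  zip_ids <- character(0)
  if (!is.null(zips) &&
      need(zips, "zip_areas.csv",
           c("zip_id", "pop_commercial", "pop_medicaid", "pop_uninsured",
             "sdoh"))) {
    zip_ids <- zips$zip_id
    for (i in which(duplicated(zips$zip_id))) {
      note("zip_areas.csv", i, "unique_zip_id",
           paste("duplicated zip_id", zips$zip_id[i]))
    }
    pops <- zips$pop_commercial + zips$pop_medicaid + zips$pop_uninsured
    for (i in which(zips$pop_commercial < 0 | zips$pop_medicaid < 0 |
                      zips$pop_uninsured < 0 | !is.finite(pops))) {
      note("zip_areas.csv", i, "population_range",
           "stratum populations must be nonnegative")
    }
  }

  ref <- read("reference_discharges.csv")
  if (!is.null(ref) &&
      need(ref, "reference_discharges.csv",
           c("zip_id", "procedure_id", "stratum", "count"))) {
    for (i in which(!ref$stratum %in% STRATA)) {
      note("reference_discharges.csv", i, "stratum_label",
           paste("unknown stratum", ref$stratum[i]))
    }
    for (i in which(ref$count < 0 | ref$count != round(ref$count))) {
      note("reference_discharges.csv", i, "count_range",
           "count must be a nonnegative integer")
    }
    for (i in which(!ref$zip_id %in% zip_ids)) {
      note("reference_discharges.csv", i, "referential_integrity",
           paste("zip_id", ref$zip_id[i], "not in zip_areas.csv"))
    }
  }

  enr <- read("claims_enrollment.csv")
  enr_ids <- character(0)
  if (!is.null(enr) &&
      need(enr, "claims_enrollment.csv",
           c("enrollee_id", "zip_id", "coverage_days"))) {
    enr_ids <- enr$enrollee_id
    for (i in which(duplicated(enr$enrollee_id))) {
      note("claims_enrollment.csv", i, "unique_enrollee_id",
           paste("duplicated enrollee_id", enr$enrollee_id[i]))
    }
    for (i in which(enr$coverage_days < 1 | enr$coverage_days > 365)) {
      note("claims_enrollment.csv", i, "coverage_range",
           sprintf("coverage_days %s outside [1, 365]", enr$coverage_days[i]))
    }
    for (i in which(!enr$zip_id %in% zip_ids)) {
      note("claims_enrollment.csv", i, "referential_integrity",
           paste("zip_id", enr$zip_id[i], "not in zip_areas.csv"))
    }
  }

  cla <- read("claims_discharges.csv")
  if (!is.null(cla) &&
      need(cla, "claims_discharges.csv",
           c("zip_id", "procedure_id", "count"))) {
    for (i in which(cla$count < 0 | cla$count != round(cla$count))) {
      note("claims_discharges.csv", i, "count_range",
           "count must be a nonnegative integer")
    }
    for (i in which(!cla$zip_id %in% zip_ids)) {
      note("claims_discharges.csv", i, "referential_integrity",
           paste("zip_id", cla$zip_id[i], "not in zip_areas.csv"))
    }
  }

  if (length(violations) == 0L) {
    tibble::tibble(file = character(), row = integer(), rule = character(),
                   message = character())
  } else {
    dplyr::bind_rows(violations)
  }
}
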