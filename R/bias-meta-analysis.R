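#' Log-linear meta-regression of relative bias on SDOH slopes
#'
#' Second-stage regression across procedures: ordinary least squares of
#' `log(relative bias)` on the per-procedure SDOH slope `beta1` (natural log
#' throughout). A negative slope means procedures concentrated in
#' high-metric (deprived, under NDI orientation) zips are systematically
#' underestimated by the claims cohort. R-squared gives the fraction of the
#' variation in log bias explained by the SDOH association.
#'
#' Unweighted by default; `weights = TRUE` switches to inverse-variance
#' weights `1 / (1/claims_count + 1/reference_count)` from the delta method
#' (requires those count columns). Nonpositive ratios (zero claims counts)
#' cannot enter a log-scale fit and are excluded with a machine-parseable
#' warning.
#'
#' @param points Tibble with columns `beta1` and `ratio` (e.g. the join of
#'   [fit_sdoh_slopes()] and [relative_bias()]); optional `procedure_id`,
#'   `claims_count`, `reference_count`.
#' @param weights Use delta-method inverse-variance weights (default FALSE).
#' @param target Label stored on the fit (`"all"`, `"insured"`,
#'   `"commercial"`, or any tag).
#' @return An object of class `bias_meta_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n_procedures`, `n_excluded`,
#'   `target`, the underlying `lm` fit, and the point data used. [tidy()],
#'   [glance()] and [autoplot()] methods are provided.
#' @export
fit_loglinear <- function(points, weights = FALSE, target = "all") {
  assert_columns(points, c("beta1", "ratio"), "points")
  if (!"procedure_id" %in% names(points)) {
    points$procedure_id <- zero_pad_ids("p", nrow(points))
  }
  all_ids <- sort(points$procedure_id)

  usable <- is.finite(points$beta1) & is.finite(points$ratio) &
    points$ratio > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    warn(sprintf("excluded_points n=%d reason=nonpositive_or_missing",
                 n_excluded))
  }
  pts <- points[usable, , drop = FALSE]
  if (nrow(pts) < 3L) {
    abort(sprintf("Need >= 3 usable points; have %d.", nrow(pts)))
  }

  df <- tibble::tibble(
    procedure_id = pts$procedure_id,
    beta1 = pts$beta1,
    log_bias = log(pts$ratio)
  )
  w <- NULL
  if (isTRUE(weights)) {
    assert_columns(pts, c("claims_count", "reference_count"), "points")
    w <- 1 / (1 / pts$claims_count + 1 / pts$reference_count)
    df$weight <- w
  }

  fit <- if (is.null(w)) {
    lm(log_bias ~ beta1, data = df)
  } else {
    lm(log_bias ~ beta1, data = df, weights = w)
  }
  # noiseless inputs trip lm's perfect-fit warning; that case is legitimate
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  ss_tot <- sum((df$log_bias - mean(df$log_bias))^2)
  r2 <- if (ss_tot == 0) 0 else sm$r.squared
  slope <- unname(coef(fit)[["beta1"]])
  p <- if (ss_tot == 0 || nrow(cf) < 2L || !is.finite(cf["beta1", 4L])) {
    1
  } else {
    cf["beta1", 4L]
  }

  structure(
    list(
      target = target,
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      se_slope = if (nrow(cf) >= 2L) unname(cf["beta1", 2L]) else NA_real_,
      r_squared = r2,
      p_value = p,
      n_procedures = nrow(df),
      n_excluded = n_excluded,
      weighted = isTRUE(weights),
      fit = fit,
      data = df,
      all_procedure_ids = all_ids
    ),
    class = "bias_meta_fit"
  )
}

#' @export
print.bias_meta_fit <- function(x, ...) {
  cat(sprintf(
    "<bias_meta_fit> target=%s: slope = %.4g (SE %.3g), R^2 = %.1f%%, p = %.3g, n = %d%s\n",
    x$target, x$slope, x$se_slope, 100 * x$r_squared, x$p_value,
    x$n_procedures,
    if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded) else ""
  ))
  invisible(x)
}

#' @export
#' @method tidy bias_meta_fit
tidy.bias_meta_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1L],
    std.error = cf[, 2L],
    statistic = cf[, 3L],
    p.value = cf[, 4L]
  )
}

#' @export
#' @method glance bias_meta_fit
glance.bias_meta_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    p_value = x$p_value,
    n_procedures = x$n_procedures,
    n_excluded = x$n_excluded
  )
}

#' @export
#' @method autoplot bias_meta_fit
autoplot.bias_meta_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$beta1, y = .data$log_bias)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "SDOH slope of the procedure (beta1)",
      y = "log relative bias (claims / reference)",
      title = sprintf("target = %s: slope %.3g, R² %.1f%%",
                      object$target, object$slope, 100 * object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Compare meta-regression fits across target populations
#'
#' Binds one row per target with the fit statistics and the distributional
#' bias summary, and reports the attenuation of the slope as the target is
#' narrowed toward the claims sampling frame
#' (`slope(commercial) / slope(all)` when both targets are present).
#'
#' @param fits Named list of [fit_loglinear()] results (names = targets), or
#'   a single fit.
#' @param summaries Optional named list of [bias_summary()] objects aligned
#'   with `fits`.
#' @return A tibble, one row per target: slope, intercept, r_squared,
#'   p_value, n_procedures, band fractions (`beyond_<factor>` columns) and
#'   IQR bounds. The attenuation ratio is stored in the `"attenuation"`
#'   attribute.
#' @export
compare_targets <- function(fits, summaries = NULL) {
  if (inherits(fits, "bias_meta_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$target, character(1))
  }
  id_sets <- lapply(fits, function(f) f$all_procedure_ids)
  if (length(unique(id_sets)) > 1L) {
    abort("Mismatched procedure sets across targets.")
  }

  out <- purrr::map_dfr(names(fits), function(tg) {
    row <- glance(fits[[tg]])
    row$target <- tg
    if (!is.null(summaries) && tg %in% names(summaries)) {
      s <- summaries[[tg]]
      for (i in seq_len(nrow(s$fractions))) {
        row[[sprintf("beyond_%g", s$fractions$factor[i])]] <-
          s$fractions$fraction_beyond[i]
      }
      row$iqr_q1 <- s$iqr[["q1"]]
      row$iqr_q3 <- s$iqr[["q3"]]
    }
    row
  })
  if (all(c("all", "commercial") %in% out$target)) {
    attr(out, "attenuation") <-
      out$slope[out$target == "commercial"] / out$slope[out$target == "all"]
  }
  out
}
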