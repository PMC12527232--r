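#' Relative bias of claims-derived rates with delta-method intervals
#'
#' The relative bias for a procedure is the claims-derived rate divided by
#' the reference (ground-truth) rate: 1 means the claims cohort reproduces
#' the target-population rate, below 1 underestimation, above 1
#' overestimation. The 95% interval propagates the two Poisson errors with
#' the delta method on the log of the ratio:
#' `exp(log(ratio) +/- z * sqrt(1/claims_count + 1/reference_count))`,
#' exposures treated as fixed.
#'
#' Procedures with a zero claims count get `ratio = 0`, a one-sided interval
#' whose upper limit comes from the exact claims-side Garwood bound, and
#' `zero_claims = TRUE` so downstream log-scale fits can exclude them.
#'
#' @param claims_rates,reference_rates Rate tibbles from [estimate_rates()]
#'   (columns procedure_id, count, person_years, rate); joined on
#'   `procedure_id`.
#' @param conf_level Confidence level.
#' @return A tibble: `procedure_id`, `ratio`, `ci_low`, `ci_high`,
#'   `claims_count`, `reference_count`, `zero_claims`.
#' @export
#' @examples
#' claims <- estimate_rate(114756, 2756043 * 303.6 / 365)
#' reference <- estimate_rate(2945667, 42062788)
#' relative_bias(claims, reference)
relative_bias <- function(claims_rates, reference_rates, conf_level = 0.95) {
  assert_columns(claims_rates, c("procedure_id", "rate"), "claims_rates")
  assert_columns(reference_rates, c("procedure_id", "rate"), "reference_rates")
  df <- dplyr::inner_join(claims_rates, reference_rates,
                          by = "procedure_id",
                          suffix = c("_claims", "_reference"))
  if (nrow(df) == 0L) abort("No procedures shared between the two rate tables.")
  if (any(df$rate_reference <= 0)) {
    abort(sprintf(
      "Reference rate is zero for procedure(s): %s; relative bias undefined.",
      paste(head(df$procedure_id[df$rate_reference <= 0], 5L), collapse = ", ")
    ))
  }

  z <- qnorm(1 - (1 - conf_level) / 2)
  ratio <- df$rate_claims / df$rate_reference
  se_log <- sqrt(1 / df$count_claims + 1 / df$count_reference)
  ci_low <- ratio * exp(-z * se_log)
  ci_high <- ratio * exp(z * se_log)

  zero <- !is.na(df$count_claims) & df$count_claims == 0
  if (any(zero)) {
    upper_count <- poisson_count_ci(0, conf_level)$upper
    ci_low[zero] <- 0
    ci_high[zero] <- (upper_count / df$person_years_claims[zero]) /
      df$rate_reference[zero]
  }

  tibble::tibble(
    procedure_id = df$procedure_id,
    ratio = ratio,
    ci_low = ci_low,
    ci_high = ci_high,
    claims_count = df$count_claims,
    reference_count = df$count_reference,
    zero_claims = zero
  )
}

#' Fraction of procedures biased beyond given factors
#'
#' A procedure is "beyond factor f" when its relative bias is at least f or
#' at most 1/f -- the definition is symmetric in over- and underestimation,
#' so it is unchanged if every ratio is replaced by its reciprocal.
#'
#' @param biases Tibble from [relative_bias()] (needs a `ratio` column).
#' @param factors Numeric thresholds, all > 1.
#' @return A tibble: `factor`, `fraction_beyond`.
#' @export
bias_band_fractions <- function(biases, factors = c(1.5, 2)) {
  assert_columns(biases, "ratio", "biases")
  if (nrow(biases) == 0L) abort("`biases` is empty.")
  if (any(!is.finite(factors)) || any(factors <= 1)) {
    abort("`factors` must all be > 1.")
  }
  r <- biases$ratio
  tibble::tibble(
    factor = factors,
    fraction_beyond = vapply(
      factors, function(f) mean(r >= f | r <= 1 / f), numeric(1)
    )
  )
}

#' Interquartile range of the relative biases
#'
#' Quartiles by linear interpolation (`stats::quantile()` type 7).
#'
#' @param biases Tibble with a `ratio` column; at least 4 values.
#' @return A named numeric vector `c(q1, q3)`.
#' @export
bias_iqr <- function(biases) {
  assert_columns(biases, "ratio", "biases")
  if (nrow(biases) < 4L) abort("Need at least 4 relative biases for an IQR.")
  q <- quantile(biases$ratio, probs = c(0.25, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Distributional summary of relative biases
#'
#' @inheritParams bias_band_fractions
#' @return An object of class `bias_summary`: list with `fractions` (from
#'   [bias_band_fractions()]), `iqr` (from [bias_iqr()]) and `n_procedures`.
#' @export
bias_summary <- function(biases, factors = c(1.5, 2)) {
  structure(
    list(
      fractions = bias_band_fractions(biases, factors),
      iqr = bias_iqr(biases),
      n_procedures = nrow(biases)
    ),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> %d procedures; IQR [%.3f, %.3f]\n",
              x$n_procedures, x$iqr[["q1"]], x$iqr[["q3"]]))
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  beyond factor %.2f: %.1f%%\n",
                x$fractions$factor[i], 100 * x$fractions$fraction_beyond[i]))
  }
  invisible(x)
}

#' Forest-plot table of relative biases
#'
#' Rows sorted ascending by the bias ratio (the magnitude ordering of a
#' forest plot), ties broken by `procedure_id`; keeps the CI columns for
#' plotting.
#'
#' @param biases Tibble from [relative_bias()].
#' @return The same tibble, sorted, with a `rank` column prepended.
#' @export
forest_table <- function(biases) {
  assert_columns(biases, c("procedure_id", "ratio"), "biases")
  out <- dplyr::arrange(biases, .data$ratio, .data$procedure_id)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Forest plot of per-procedure relative bias
#'
#' @param biases Tibble from [relative_bias()].
#' @param max_labels Label the procedure axis only when there are at most
#'   this many procedures.
#' @return A ggplot.
#' @export
plot_forest <- function(biases, max_labels = 40) {
  ft <- forest_table(biases)
  p <- ggplot2::ggplot(
    ft,
    ggplot2::aes(x = .data$ratio, y = .data$rank)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0, colour = "grey60", na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Relative bias (claims / reference), log scale",
      y = "Procedures, ordered by bias"
    ) +
    ggplot2::theme_minimal()
  if (nrow(ft) <= max_labels) {
    p <- p + ggplot2::scale_y_continuous(
      breaks = ft$rank, labels = ft$procedure_id
    )
  }
  p
}
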