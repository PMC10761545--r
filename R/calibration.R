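#' Integrated MS1 intensity ratio for one run
#'
#' The quantity of record of the whole pipeline: the sum of all present
#' host-group MS1 intensities in a run divided by the sum of all present
#' target-group intensities. The target protein's own summed intensity acts
#' as a pseudo internal standard, cancelling run-to-run variation in injected
#' amount and instrument response; the ratio is therefore invariant to
#' rescaling all intensities of a run by a common factor. Missing cells
#' (protein not identified in that run) contribute nothing to either sum.
#'
#' @param table An intensity-table tibble (see [read_intensity_table()]).
#' @param groups A group assignment from [assign_groups()].
#' @param run_id Name of the run column to use.
#' @return A one-row tibble with columns `run_id`, `R` (dimensionless ratio),
#'   `S_host`, `S_target` (summed intensities).
#' @export
compute_ratio <- function(table, groups, run_id) {
  table <- validate_intensity_table(table)
  if (!run_id %in% intensity_runs(table)) {
    abort(paste0("run '", run_id, "' not in table"), class = "hcp_validation_error")
  }
  g <- groups$group[match(table$accession, groups$accession)]
  v <- table[[run_id]]
  s_target <- sum(v[g == "target"], na.rm = TRUE)
  n_target_present <- sum(g == "target" & !is.na(v))
  if (n_target_present == 0 || s_target <= 0) {
    abort(paste0("run '", run_id, "': no target intensity present; ratio undefined"),
      class = "hcp_ratio_error"
    )
  }
  s_host <- sum(v[g == "host"], na.rm = TRUE)
  tibble::tibble(
    run_id = run_id, R = s_host / s_target,
    S_host = s_host, S_target = s_target
  )
}

#' Intensity ratios for several runs
#'
#' Applies [compute_ratio()] to each requested run and row-binds the results.
#'
#' @inheritParams compute_ratio
#' @param run_ids Run column names; default all runs in the table.
#' @return A tibble with one row per run (`run_id`, `R`, `S_host`, `S_target`).
#' @export
compute_ratios <- function(table, groups, run_ids = NULL) {
  run_ids <- run_ids %||% intensity_runs(table)
  purrr::map_dfr(run_ids, function(r) compute_ratio(table, groups, r))
}

#' Fit the linear calibration of intensity ratio on mass fraction
#'
#' Ordinary unweighted least squares of the ratio R on the known calibrant
#' mass fraction w (mg/g), with intercept. Every LC-MS run is one calibration
#' point: replicates at a level enter as separate observations and are
#' counted in n. Besides the line, the model stores the sufficient statistics
#' needed for inverse-prediction uncertainty: the residual standard deviation
#' `s_yx`, `n`, the means of w and R, and `S_xx` = sum((w - mean(w))^2), with
#' `df = n - 2`.
#'
#' @param points A data frame with columns `w_known` (mg/g) and `R`, one row
#'   per calibration run. Extra columns are kept in `model$points`.
#' @param source_label Optional name of the calibrant proteome, carried into
#'   reports and plots.
#' @return An object of class `hcp_calibration`: a list with elements
#'   `a` (intercept), `b` (slope, per mg/g), `s_yx`, `n`, `x_bar`, `y_bar`,
#'   `S_xx`, `df`, `r_squared`, `source_label` and the `points` tibble.
#' @seealso [predict_mass_fraction()], [tidy.hcp_calibration()],
#'   [autoplot.hcp_calibration()]
#' @export
fit_calibration <- function(points, source_label = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("w_known", "R") %in% names(points)))
  if (any(!is.finite(points$R)) || any(!is.finite(points$w_known))) {
    abort("non-finite calibration point", class = "hcp_validation_error")
  }
  n <- nrow(points)
  n_levels <- length(unique(points$w_known))
  if (n_levels < 2) {
    abort("all w_known identical: singular design", class = "hcp_singular_error")
  }
  if (n_levels < 3) {
    abort("at least 3 distinct calibration levels required",
      class = "hcp_insufficient_data_error"
    )
  }
  fit <- lm(R ~ w_known, data = points)
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  res <- points$R - (a + b * points$w_known)
  df <- n - 2L
  s_yx <- sqrt(sum(res^2) / df)
  y_bar <- mean(points$R)
  tss <- sum((points$R - y_bar)^2)
  structure(
    list(
      a = a, b = b, s_yx = s_yx, n = n,
      x_bar = mean(points$w_known), y_bar = y_bar,
      S_xx = sum((points$w_known - mean(points$w_known))^2),
      df = df,
      r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
      source_label = source_label %||% "calibrant",
      points = points
    ),
    class = "hcp_calibration"
  )
}

#' @export
print.hcp_calibration <- function(x, ...) {
  cat("Linear MS1-ratio calibration (", x$source_label, ")\n", sep = "")
  cat(sprintf(
    "  R = %.6g + %.6g * w   [n = %d, df = %d, s_yx = %.4g, r^2 = %.4f]\n",
    x$a, x$b, x$n, x$df, x$s_yx, x$r_squared
  ))
  invisible(x)
}

#' @describeIn fit_calibration Per-point tidy summary: one row per
#'   calibration point with its fitted ratio and residual.
#' @exportS3Method generics::tidy
tidy.hcp_calibration <- function(x, ...) {
  x$points |>
    dplyr::mutate(
      fitted = x$a + x$b * .data$w_known,
      residual = .data$R - .data$fitted
    )
}

#' @describeIn fit_calibration One-row model summary (intercept, slope,
#'   residual SD, n, df, r^2).
#' @exportS3Method generics::glance
glance.hcp_calibration <- function(x, ...) {
  tibble::tibble(
    source_label = x$source_label,
    intercept = x$a, slope = x$b, s_yx = x$s_yx,
    n = x$n, df = x$df, r_squared = x$r_squared,
    x_bar = x$x_bar, y_bar = x$y_bar, S_xx = x$S_xx
  )
}

#' Inverse prediction of an unknown impurity mass fraction
#'
#' Solves the fitted calibration line for the mass fraction given the
#' observed intensity ratio(s) of a sample: `w0 = (ybar0 - a) / b` with
#' `ybar0` the mean of the m sample ratios. The standard uncertainty of the
#' prediction follows the standard inverse-calibration approximation
#'
#' \deqn{s_{x0} = \frac{s_{yx}}{b}\sqrt{\frac{1}{m} + \frac{1}{n} +
#'   \frac{(\bar y_0 - \bar y)^2}{b^2 S_{xx}}}}
#'
#' combining sample replication (m), calibration size (n) and leverage of the
#' sample ratio relative to the calibration's centroid.
#'
#' @param model An `hcp_calibration` from [fit_calibration()].
#' @param ratios Numeric vector of sample intensity ratios (one per sample
#'   run, averaged on the ratio scale).
#' @return A one-row tibble: `w0` (mg/g), `s_x0` (mg/g), `u_meas_rel`
#'   (percent, `100 * s_x0 / w0`), `m`, `df` (the calibration's), and logical
#'   flags `outside_support` (w0 beyond the calibrated range; extrapolation
#'   is flagged, not forbidden) and `below_zero` (w0 <= 0, i.e. the ratio
#'   fell below the fitted blank).
#' @export
predict_mass_fraction <- function(model, ratios) {
  stopifnot(inherits(model, "hcp_calibration"))
  ratios <- as.numeric(ratios)
  m <- length(ratios)
  if (m < 1 || any(!is.finite(ratios))) {
    abort("need at least one finite sample ratio", class = "hcp_validation_error")
  }
  if (!is.finite(model$b) || model$b <= 0) {
    abort("calibration slope must be positive for inverse prediction",
      class = "hcp_validation_error"
    )
  }
  y0 <- mean(ratios)
  w0 <- (y0 - model$a) / model$b
  s_x0 <- (model$s_yx / model$b) *
    sqrt(1 / m + 1 / model$n + (y0 - model$y_bar)^2 / (model$b^2 * model$S_xx))
  rng <- range(model$points$w_known)
  tol <- 1e-9 * diff(rng)
  outside <- w0 < rng[1] - tol || w0 > rng[2] + tol
  below <- w0 <= 0
  if (below) {
    warn("predicted mass fraction is <= 0: sample ratio below the fitted blank")
  } else if (outside) {
    warn(sprintf(
      "predicted mass fraction %.4g mg/g lies outside the calibrated range [%.4g, %.4g]",
      w0, rng[1], rng[2]
    ))
  }
  tibble::tibble(
    w0 = w0, s_x0 = s_x0,
    u_meas_rel = if (w0 > 0) 100 * s_x0 / w0 else NA_real_,
    m = m, df = model$df,
    outside_support = outside, below_zero = below
  )
}

#' Calibration scatter plot with fitted line
#'
#' @param object An `hcp_calibration`.
#' @param ... Ignored.
#' @return A ggplot: calibration points, fitted line, annotated with the
#'   calibrant source and r^2.
#' @exportS3Method ggplot2::autoplot
autoplot.hcp_calibration <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$w_known, y = .data$R)) +
    ggplot2::geom_abline(
      intercept = object$a, slope = object$b,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "known mass fraction w (mg/g)",
      y = "MS1 intensity ratio R (host / target)",
      title = sprintf(
        "%s calibration (n = %d, r² = %.3f)",
        object$source_label, object$n, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}
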