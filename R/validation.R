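#' Leave-one-out cross-validation of a calibration
#'
#' For each calibration point i, the line is refitted on the remaining points
#' and the left-out ratio is inverse-predicted; the relative prediction error
#' `(w_hat - w_i) / w_i * 100` is recorded. The headline dispersion figure is
#' the median of these errors (robust to fliers); quartiles use R's default
#' linear-interpolation (inclusive-median) method and fliers are points
#' beyond 1.5 IQR from the quartiles, as in a standard boxplot.
#'
#' @param points A data frame with columns `w_known` and `R`, one row per
#'   calibration run (at least 4 rows, so each reduced fit keeps >= 3).
#' @return An object of class `hcp_cv`: list with `errors` (tibble: `index`,
#'   `w_known`, `R`, `w_pred`, `rel_error_pct`, `skipped`), `median`, `q1`,
#'   `q3`, `fliers` (indices), `median_abs_error`, `n_skipped`.
#' @export
loo_cv <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("w_known", "R") %in% names(points)))
  n <- nrow(points)
  if (n < 4) {
    abort("leave-one-out cross-validation needs at least 4 points",
      class = "hcp_insufficient_data_error"
    )
  }
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    rest <- points[-i, ]
    fit <- tryCatch(fit_calibration(rest), error = function(e) NULL)
    if (is.null(fit) || fit$b <= 0) {
      warn(sprintf("point %d skipped: reduced design not fittable", i))
      return(tibble::tibble(
        index = i, w_known = points$w_known[i], R = points$R[i],
        w_pred = NA_real_, rel_error_pct = NA_real_, skipped = TRUE
      ))
    }
    w_pred <- (points$R[i] - fit$a) / fit$b
    tibble::tibble(
      index = i, w_known = points$w_known[i], R = points$R[i],
      w_pred = w_pred,
      rel_error_pct = 100 * (w_pred - points$w_known[i]) / points$w_known[i],
      skipped = FALSE
    )
  })
  err <- rows$rel_error_pct[!rows$skipped]
  qs <- quantile(err, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  # guard against flagging numerical jitter when all errors are essentially 0
  eps <- sqrt(.Machine$double.eps) * max(1, abs(qs[2]))
  fliers <- rows$index[!rows$skipped &
    (rows$rel_error_pct < qs[1] - 1.5 * iqr - eps |
      rows$rel_error_pct > qs[3] + 1.5 * iqr + eps)]
  structure(
    list(
      errors = rows,
      median = qs[2], q1 = qs[1], q3 = qs[3],
      fliers = fliers,
      median_abs_error = median(abs(err)),
      n_skipped = sum(rows$skipped)
    ),
    class = "hcp_cv"
  )
}

#' @export
print.hcp_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out CV over %d points: median error %.3g %% (IQR %.3g to %.3g %%), %d flier(s)\n",
    nrow(x$errors), x$median, x$q1, x$q3, length(x$fliers)
  ))
  invisible(x)
}

#' @describeIn loo_cv Per-point errors as a tibble.
#' @exportS3Method generics::tidy
tidy.hcp_cv <- function(x, ...) x$errors

#' @describeIn loo_cv One-row summary (median, quartiles, median absolute
#'   error, flier and skip counts).
#' @exportS3Method generics::glance
glance.hcp_cv <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$errors), median = x$median, q1 = x$q1, q3 = x$q3,
    median_abs_error = x$median_abs_error,
    n_fliers = length(x$fliers), n_skipped = x$n_skipped
  )
}

#' Boxplot of leave-one-out prediction errors
#'
#' @param object An `hcp_cv`.
#' @param ... Ignored.
#' @return A ggplot boxplot of the relative prediction errors with the median
#'   annotated.
#' @exportS3Method ggplot2::autoplot
autoplot.hcp_cv <- function(object, ...) {
  df <- dplyr::filter(object$errors, !.data$skipped)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$rel_error_pct)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5) +
    ggplot2::annotate("text",
      x = 1.3, y = object$median,
      label = sprintf("median %.2g%%", object$median), colour = "darkorange"
    ) +
    ggplot2::labs(x = NULL, y = "LOO relative prediction error (%)") +
    ggplot2::theme_minimal()
}

#' Pool calibration series from different calibrant sources
#'
#' Concatenates the calibration points of two or more series (e.g. a
#' bacterial lysate, a yeast lysate and a defined protein mix) and fits one
#' common line, treating the series as samples from a common statistical
#' population; the pooled degrees of freedom are total n - 2. Per-series
#' fits are retained for an equivalence summary.
#'
#' @param series A named or unnamed list whose elements are either point data
#'   frames (columns `w_known`, `R`) or fitted `hcp_calibration` objects.
#' @param source_label Label for the pooled model (default `"pooled"`).
#' @return An `hcp_calibration` for the pooled fit, with an extra element
#'   `per_series`: a tibble of per-series intercepts, slopes and fit
#'   statistics from [glance()].
#' @export
pool_calibrations <- function(series, source_label = "pooled") {
  if (length(series) < 2) {
    abort("pooling needs at least 2 series", class = "hcp_validation_error")
  }
  labels <- names(series) %||% paste0("series", seq_along(series))
  labels[!nzchar(labels)] <- paste0("series", which(!nzchar(labels)))
  pts <- purrr::map(series, function(s) {
    if (inherits(s, "hcp_calibration")) s$points else tibble::as_tibble(s)
  })
  fits <- purrr::map2(pts, labels, function(p, lb) fit_calibration(p, source_label = lb))
  pooled <- fit_calibration(
    dplyr::bind_rows(setNames(pts, labels), .id = "series"),
    source_label = source_label
  )
  pooled$per_series <- purrr::map_dfr(fits, glance)
  pooled
}
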