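#' Summarize replicate impurity results
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' replicate label-free quantification results for one material.
#'
#' @param results Numeric vector of impurity mass fractions (mg/g), one per
#'   replicate determination.
#' @return A one-row tibble: `mean` (mg/g), `sd` (mg/g, `NA` for n = 1), `n`.
#' @export
summarize_replicates <- function(results) {
  results <- as.numeric(results)
  if (length(results) == 0 || any(!is.finite(results))) {
    abort("need at least one finite replicate result", class = "hcp_validation_error")
  }
  tibble::tibble(
    mean = mean(results),
    sd = if (length(results) >= 2) sd(results) else NA_real_,
    n = length(results)
  )
}

#' Expand a standard uncertainty with a Student-t coverage factor
#'
#' Converts a standard relative uncertainty into an expanded ~95 % uncertainty
#' using the two-sided 95 % Student-t quantile at the calibration's residual
#' degrees of freedom as coverage factor k.
#'
#' @param u_rel Standard relative uncertainty, percent.
#' @param df Degrees of freedom (for a calibration with n points, n - 2).
#' @return A one-row tibble: `k` and `U_rel` (= k * u_rel, percent, carried at
#'   full precision).
#' @export
expand_uncertainty <- function(u_rel, df) {
  if (!is.finite(u_rel) || u_rel < 0) {
    abort("u_rel must be >= 0", class = "hcp_domain_error")
  }
  if (!is.finite(df) || df < 1) {
    abort("df must be >= 1", class = "hcp_domain_error")
  }
  k <- qt(0.975, df)
  tibble::tibble(k = k, U_rel = k * u_rel)
}

#' Combine measurement and calibrator uncertainty into the impurity budget
#'
#' Root-sum-square combination of the two independent expanded relative
#' uncertainty components: the inverse-prediction (measurement) component and
#' the calibrator value-assignment component. Because the two components
#' carry different coverage factors (a Student-t k for the measurement, a
#' normal k of about 2 for the 95 % AAA value assignment), the combination is
#' performed on the standard-uncertainty scale and re-expanded with the
#' measurement's k:
#'
#' \deqn{U_{imp} = k \sqrt{(U_{meas}/k)^2 + (U_{cal}/k_{cal})^2}}
#'
#' With `k = k_cal` this reduces to the plain root-sum-square of the expanded
#' values, \eqn{U_{imp}^2 = U_{meas}^2 + U_{cal}^2}.
#'
#' @param U_meas_rel Expanded relative measurement uncertainty, percent.
#' @param U_cal_rel Expanded (95 %) relative calibrator uncertainty, percent.
#' @param k Coverage factor behind `U_meas_rel` (Student-t); default 2.
#' @param k_cal Coverage factor behind `U_cal_rel`; default 2.
#' @return Combined expanded relative uncertainty on the impurity, percent.
#' @export
combine_budget <- function(U_meas_rel, U_cal_rel, k = 2, k_cal = 2) {
  if (any(!is.finite(c(U_meas_rel, U_cal_rel))) || U_meas_rel < 0 || U_cal_rel < 0) {
    abort("uncertainty components must be >= 0", class = "hcp_domain_error")
  }
  k * sqrt((U_meas_rel / k)^2 + (U_cal_rel / k_cal)^2)
}

#' Convert an impurity mass fraction to purity with confidence interval
#'
#' Converts w, the impurity mass fraction per mass of target protein (mg
#' impurity / g target), into the purity on a total-protein basis,
#' \eqn{P = 1000 / (1 + w/1000)} mg target / g total protein. The purity
#' confidence interval is obtained by transforming the endpoints of the
#' symmetric expanded interval on the impurity, `w * (1 -+ U/100)`; because
#' the transform is convex the purity interval is asymmetric around P.
#'
#' @param w_imp Impurity mass fraction, mg/g (vectorized).
#' @param U_imp_rel Combined expanded relative uncertainty on the impurity,
#'   percent (vectorized; recycled against `w_imp`).
#' @return A tibble of class `hcp_purity`, one row per input: `w_imp`,
#'   `U_imp_rel`, `U_imp_abs` (mg/g), `w_lo`, `w_hi`, `purity` (mg/g total
#'   protein), `purity_lo`, `purity_hi`, `U_purity_rel` (percent, half-width
#'   of the purity interval over the purity). For `w_imp = 0` the purity is
#'   exactly 1000 with a degenerate interval.
#' @export
impurity_to_purity <- function(w_imp, U_imp_rel) {
  if (any(!is.finite(w_imp)) || any(w_imp < 0)) {
    abort("w_imp must be >= 0", class = "hcp_domain_error")
  }
  if (any(!is.finite(U_imp_rel)) || any(U_imp_rel < 0)) {
    abort("U_imp_rel must be >= 0", class = "hcp_domain_error")
  }
  n <- max(length(w_imp), length(U_imp_rel))
  w_imp <- rep_len(w_imp, n)
  U_imp_rel <- rep_len(U_imp_rel, n)
  w_lo <- pmax(w_imp * (1 - U_imp_rel / 100), 0)
  w_hi <- w_imp * (1 + U_imp_rel / 100)
  purity <- 1000 / (1 + w_imp / 1000)
  purity_lo <- 1000 / (1 + w_hi / 1000)
  purity_hi <- 1000 / (1 + w_lo / 1000)
  out <- tibble::tibble(
    w_imp = w_imp, U_imp_rel = U_imp_rel,
    U_imp_abs = w_imp * U_imp_rel / 100,
    w_lo = w_lo, w_hi = w_hi,
    purity = purity, purity_lo = purity_lo, purity_hi = purity_hi,
    U_purity_rel = ifelse(purity > 0, 100 * (purity_hi - purity_lo) / 2 / purity, NA_real_)
  )
  class(out) <- c("hcp_purity", class(out))
  out
}

#' End-to-end value assignment: ratio to purity with full budget
#'
#' Chains the whole value-assignment arithmetic for one material: inverse
#' prediction of the impurity mass fraction from the sample's intensity
#' ratios, t-expansion of the measurement uncertainty at the calibration's
#' degrees of freedom, combination with the calibrator value-assignment
#' uncertainty, and conversion to purity. Every intermediate is carried at
#' full precision and reported.
#'
#' @param model An `hcp_calibration` from [fit_calibration()].
#' @param ratios Numeric vector of sample intensity ratios (m runs).
#' @param U_cal_rel Expanded (95 %) relative uncertainty of the calibrator
#'   value assignment, percent.
#' @param k_cal Coverage factor behind `U_cal_rel`; default 2.
#' @return An object of class `hcp_budget`: a list with `prediction` (the
#'   [predict_mass_fraction()] row), scalars `w_imp`, `u_meas_rel`, `k`,
#'   `df`, `U_meas_rel`, `U_cal_rel`, `U_imp_rel`, and `purity` (the
#'   [impurity_to_purity()] row). [glance()] flattens it to one row.
#' @export
run_value_assignment <- function(model, ratios, U_cal_rel, k_cal = 2) {
  pred <- predict_mass_fraction(model, ratios)
  if (pred$below_zero) {
    abort("predicted impurity <= 0; budget undefined below calibration support",
      class = "hcp_domain_error"
    )
  }
  exp_ <- expand_uncertainty(pred$u_meas_rel, model$df)
  U_imp <- combine_budget(exp_$U_rel, U_cal_rel, k = exp_$k, k_cal = k_cal)
  purity <- impurity_to_purity(pred$w0, U_imp)
  structure(
    list(
      prediction = pred,
      w_imp = pred$w0,
      u_meas_rel = pred$u_meas_rel,
      k = exp_$k, df = model$df,
      U_meas_rel = exp_$U_rel,
      U_cal_rel = U_cal_rel,
      U_imp_rel = U_imp,
      purity = purity,
      source_label = model$source_label
    ),
    class = "hcp_budget"
  )
}

#' @export
print.hcp_budget <- function(x, ...) {
  cat("Impurity value assignment (", x$source_label, " calibration)\n", sep = "")
  cat(sprintf(
    "  w_imp     = %.4g mg/g  (m = %d sample runs)\n",
    x$w_imp, x$prediction$m
  ))
  cat(sprintf(
    "  u_meas    = %.3g %%   U_meas = %.3g %% (k = %.3g, df = %d)\n",
    x$u_meas_rel, x$U_meas_rel, x$k, x$df
  ))
  cat(sprintf(
    "  U_cal     = %.3g %%   U_imp  = %.3g %%\n",
    x$U_cal_rel, x$U_imp_rel
  ))
  cat(sprintf(
    "  purity    = %.4g mg/g total protein, CI [%.4g, %.4g]  (+/- %.2g %%)\n",
    x$purity$purity, x$purity$purity_lo, x$purity$purity_hi, x$purity$U_purity_rel
  ))
  invisible(x)
}

#' @describeIn run_value_assignment One-row tibble of every budget
#'   intermediate.
#' @exportS3Method generics::glance
glance.hcp_budget <- function(x, ...) {
  tibble::tibble(
    source_label = x$source_label,
    w_imp = x$w_imp, m = x$prediction$m,
    u_meas_rel = x$u_meas_rel, k = x$k, df = x$df,
    U_meas_rel = x$U_meas_rel, U_cal_rel = x$U_cal_rel,
    U_imp_rel = x$U_imp_rel,
    purity = x$purity$purity,
    purity_lo = x$purity$purity_lo, purity_hi = x$purity$purity_hi,
    U_purity_rel = x$purity$U_purity_rel,
    outside_support = x$prediction$outside_support
  )
}
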