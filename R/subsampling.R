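#' Protein-subsampling error simulation
#'
#' Estimates the sampling error induced by calibrating with a finite number
#' of proteins. For each subset size n below the full calibrant count K, the
#' calibration is re-derived from random drafts of n calibrant proteins: each
#' calibration run's ratio is recomputed with only the drafted proteins in
#' the numerator (the target denominator is untouched), the known mass
#' fractions are rescaled by the drafted proteins' mass share when the design
#' provides per-protein masses, the line is refitted and the sample's
#' impurity mass fraction re-predicted. Per subset size the median and
#' standard deviation of the predictions are reported, the SD relative to the
#' full-set prediction.
#'
#' Drafts are uniform without replacement and each (n, draft) pair uses its
#' own pseudo-random substream derived from the master seed, so results are
#' bit-reproducible and independent of execution order. A draft whose
#' proteins carry zero intensity in some calibration run is resampled and the
#' occurrence counted.
#'
#' @param calib_table Calibration intensity table (per-protein resolution).
#' @param groups Group assignment for the calibration table; the `"host"`
#'   group is the calibrant.
#' @param design An `hcp_design` covering the calibration runs; if it carries
#'   a `mass_shares` attribute, drafted designs rescale `w_known` by the
#'   drafted mass share (see `rescale`).
#' @param sample_table Intensity table of the material under test.
#' @param sample_groups Group assignment for the sample table; defaults to
#'   `groups`.
#' @param sample_run_ids Sample run columns; default all.
#' @param n_values Subset sizes to simulate; default `1:(K - 1)`.
#' @param n_drafts Random drafts per subset size (default 100).
#' @param seed Mandatory integer master seed.
#' @param rescale Rescale `w_known` by drafted mass share; default `TRUE`
#'   when the design has per-protein masses, otherwise `FALSE` (whole-lysate
#'   calibrants with unknown per-protein masses), with a note recorded.
#' @param exhaustive If `TRUE`, enumerate every subset of each size exactly
#'   once instead of random drafting (`n_drafts` and `seed` unused for
#'   drawing).
#' @return An object of class `hcp_subsample`: list with `draws` (tibble:
#'   `n`, `draft`, `w_pred`, `mass_share`), `summary` (tibble: `n`, `median`,
#'   `sd`, `rel_sd_pct`, `n_resampled`), `w_full` (full-calibrant
#'   prediction), `K`, `seed`, `n_drafts`, `rescaled`.
#' @seealso [sampling_error_threshold()], [autoplot.hcp_subsample()]
#' @export
subsample_experiment <- function(calib_table, groups, design, sample_table,
                                 sample_groups = groups,
                                 sample_run_ids = NULL,
                                 n_values = NULL, n_drafts = 100, seed,
                                 rescale = NULL, exhaustive = FALSE) {
  if (missing(seed)) abort("seed is mandatory", class = "hcp_validation_error")
  seed <- as.integer(seed)
  calib_table <- validate_intensity_table(calib_table)
  sample_run_ids <- sample_run_ids %||% intensity_runs(sample_table)

  host_acc <- groups$accession[groups$group == "host"]
  host_acc <- host_acc[host_acc %in% calib_table$accession]
  K <- length(host_acc)
  if (K < 2) abort("calibrant group needs >= 2 proteins", class = "hcp_validation_error")
  n_values <- n_values %||% seq_len(K - 1)
  if (any(n_values < 1 | n_values >= K)) {
    abort("n_values must lie in 1..(K-1)", class = "hcp_validation_error")
  }
  shares <- attr(design, "mass_shares")
  if (!is.null(shares)) shares <- shares[host_acc]
  rescale <- rescale %||% !is.null(shares)
  if (rescale && is.null(shares)) {
    abort("rescale = TRUE requires per-protein mass_shares in the design",
      class = "hcp_validation_error"
    )
  }

  # per-run sums at full resolution, so drafted ratios are cheap subset sums
  g <- groups$group[match(calib_table$accession, groups$accession)]
  cal_runs <- design$run_id
  host_mat <- as.matrix(calib_table[match(host_acc, calib_table$accession), cal_runs])
  host_mat[is.na(host_mat)] <- 0
  target_sum <- colSums(
    as.matrix(calib_table[g == "target", cal_runs, drop = FALSE]),
    na.rm = TRUE
  )
  if (any(target_sum <= 0)) {
    abort("calibration run without target signal", class = "hcp_ratio_error")
  }
  sample_ratios <- compute_ratios(sample_table, sample_groups, sample_run_ids)$R
  y0 <- mean(sample_ratios)

  predict_from <- function(w_known, R) {
    fit <- fit_calibration(tibble::tibble(w_known = w_known, R = R))
    (y0 - fit$a) / fit$b
  }
  w_full <- predict_from(design$w_known, colSums(host_mat) / target_sum)

  one_draft <- function(n, d) {
    n_resampled <- 0L
    repeat {
      if (exhaustive) {
        idx <- utils::combn(K, n)[, d]
      } else {
        set.seed((seed %% 1000003L) * 1009L + n * 7919L + d + n_resampled * 104729L)
        idx <- sample.int(K, n)
      }
      num <- if (n == 1) host_mat[idx, ] else colSums(host_mat[idx, , drop = FALSE])
      if (all(num > 0) || exhaustive) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 1000L) {
        abort("could not draft a subset with non-zero signal in every run",
          class = "hcp_domain_error"
        )
      }
    }
    share <- if (rescale) sum(shares[idx]) else 1
    tibble::tibble(
      n = n, draft = d,
      w_pred = predict_from(design$w_known * share, num / target_sum),
      mass_share = share, n_resampled = n_resampled
    )
  }

  draws <- purrr::map_dfr(n_values, function(n) {
    drafts <- if (exhaustive) seq_len(choose(K, n)) else seq_len(n_drafts)
    purrr::map_dfr(drafts, function(d) one_draft(n, d))
  })
  summary <- draws |>
    dplyr::group_by(n) |>
    dplyr::summarise(
      median = median(.data$w_pred),
      sd = sd(.data$w_pred),
      rel_sd_pct = 100 * sd(.data$w_pred) / .env$w_full,
      n_resampled = sum(.data$n_resampled),
      .groups = "drop"
    )
  structure(
    list(
      draws = dplyr::select(draws, -"n_resampled"),
      summary = summary,
      w_full = w_full, K = K, seed = seed,
      n_drafts = if (exhaustive) NA_integer_ else n_drafts,
      rescaled = rescale, exhaustive = exhaustive
    ),
    class = "hcp_subsample"
  )
}

#' @export
print.hcp_subsample <- function(x, ...) {
  cat(sprintf(
    "Protein-subsampling simulation: K = %d calibrant proteins, w_full = %.4g mg/g\n",
    x$K, x$w_full
  ))
  print(x$summary)
  invisible(x)
}

#' @describeIn subsample_experiment Per-draft predictions as a tibble.
#' @exportS3Method generics::tidy
tidy.hcp_subsample <- function(x, ...) x$draws

#' @describeIn subsample_experiment Per-subset-size summary tibble.
#' @exportS3Method generics::glance
glance.hcp_subsample <- function(x, ...) {
  dplyr::mutate(x$summary, w_full = x$w_full, K = x$K)
}

#' Smallest calibrant subset keeping the sampling error under a threshold
#'
#' @param result An `hcp_subsample`.
#' @param threshold_pct Acceptable relative sampling error (SD of drafted
#'   predictions over the full-set prediction), percent.
#' @return The smallest simulated subset size whose relative SD is at or
#'   under the threshold, or `NA` if none qualifies.
#' @export
sampling_error_threshold <- function(result, threshold_pct) {
  stopifnot(inherits(result, "hcp_subsample"))
  ok <- result$summary$n[result$summary$rel_sd_pct <= threshold_pct]
  if (length(ok) == 0) NA_integer_ else min(ok)
}

#' Sampling-error curve: median and SD of predictions vs subset size
#'
#' @param object An `hcp_subsample`.
#' @param guide_pct Dashed guide lines at the full-set prediction
#'   +/- this percentage (default 15).
#' @param ... Ignored.
#' @return A ggplot of drafted-prediction medians with an SD ribbon around
#'   the full-set value.
#' @exportS3Method ggplot2::autoplot
autoplot.hcp_subsample <- function(object, guide_pct = 15, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = object$w_full - .data$sd,
        ymax = object$w_full + .data$sd
      ),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_hline(yintercept = object$w_full) +
    ggplot2::geom_hline(
      yintercept = object$w_full * (1 + c(-1, 1) * guide_pct / 100),
      linetype = "dashed"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median)) +
    ggplot2::scale_x_continuous(breaks = s$n) +
    ggplot2::labs(
      x = "number of calibrant proteins drafted",
      y = "predicted impurity mass fraction (mg/g)"
    ) +
    ggplot2::theme_minimal()
}
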