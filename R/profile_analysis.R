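#' Signal fraction of co-purifying proteins
#'
#' The fraction of total host-protein MS1 intensity carried by a watchlist of
#' proteins known to co-purify with the target (for IMAC-purified material,
#' typically metal-binding host proteins). Computed per run as the summed
#' intensity over (host intersect watchlist) divided by the summed intensity
#' over all host proteins identified.
#'
#' @param table An intensity-table tibble.
#' @param groups A group assignment from [assign_groups()].
#' @param watchlist Character vector of accessions (normalized on matching),
#'   or the path of a one-accession-per-line file.
#' @param run_ids Run column name(s); default all runs.
#' @return A tibble, one row per run: `run_id`, `fraction` (in `[0, 1]`, `NA`
#'   when the run has zero host signal), `S_watch`, `S_host`, `defined`.
#' @export
copurified_fraction <- function(table, groups, watchlist, run_ids = NULL) {
  table <- validate_intensity_table(table)
  run_ids <- run_ids %||% intensity_runs(table)
  watchlist <- resolve_accession_input(watchlist)
  g <- groups$group[match(table$accession, groups$accession)]
  acc_norm <- normalize_accessions(table$accession)
  is_host <- g == "host"
  in_watch <- is_host & acc_norm %in% watchlist
  purrr::map_dfr(run_ids, function(r) {
    v <- table[[r]]
    s_host <- sum(v[is_host], na.rm = TRUE)
    s_watch <- sum(v[in_watch], na.rm = TRUE)
    defined <- s_host > 0
    if (!defined) warn(sprintf("run '%s': zero host signal, fraction undefined", r))
    tibble::tibble(
      run_id = r,
      fraction = if (defined) s_watch / s_host else NA_real_,
      S_watch = s_watch, S_host = s_host, defined = defined
    )
  })
}

#' Build a samples-by-proteins profile matrix
#'
#' Extracts the host-protein intensity profile of each run as a numeric
#' matrix (runs in rows, proteins in columns). Unlike the ratio statistic,
#' which skips missing cells, the profile analyses treat a missing
#' identification as zero intensity: the matrix must be complete and absence
#' is here evidence of low abundance.
#'
#' @param table An intensity-table tibble.
#' @param groups A group assignment; only `"host"` accessions enter.
#' @param run_ids Run columns to include; default all.
#' @return A numeric matrix with `run_ids` as rownames and host accessions as
#'   colnames; column order follows the table and is recorded by the names.
#' @export
profile_matrix <- function(table, groups, run_ids = NULL) {
  table <- validate_intensity_table(table)
  run_ids <- run_ids %||% intensity_runs(table)
  g <- groups$group[match(table$accession, groups$accession)]
  host <- table[g == "host", , drop = FALSE]
  m <- t(as.matrix(host[run_ids]))
  m[is.na(m)] <- 0
  dimnames(m) <- list(run_ids, host$accession)
  m
}

#' Principal component analysis of impurity protein profiles
#'
#' Column-mean-centered PCA of a samples-by-proteins intensity matrix via
#' singular value decomposition. No variance scaling is applied by default:
#' the decomposition acts on raw intensities, so abundant proteins dominate
#' the components, which is the intended reading of an impurity profile.
#' Component signs are fixed by forcing the largest-magnitude loading of each
#' component positive, so biplots are reproducible.
#'
#' @param matrix A numeric samples-by-proteins matrix (see
#'   [profile_matrix()]), at least 2 x 2.
#' @param n_components Number of leading components to highlight in plots
#'   (all components are always computed and returned).
#' @param scale. If `TRUE`, additionally scale columns to unit variance;
#'   default `FALSE`.
#' @return An object of class `hcp_pca`: list with `scores` (samples x
#'   components), `loadings` (proteins x components, orthonormal),
#'   `var_frac` (percent of variance per component, non-increasing, summing
#'   to 100), `center` (column means), `n_components`.
#' @export
pca_profiles <- function(matrix, n_components = 2, scale. = FALSE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    abort("profile PCA needs at least 2 samples and 2 proteins",
      class = "hcp_validation_error"
    )
  }
  if (scale.) {
    csd <- apply(matrix, 2, sd)
    if (any(csd == 0)) {
      abort("cannot unit-variance scale constant columns", class = "hcp_domain_error")
    }
  }
  pc <- prcomp(matrix, center = TRUE, scale. = scale.)
  scores <- pc$x
  loadings <- pc$rotation
  # sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(loadings))) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_all <- pc$sdev^2
  structure(
    list(
      scores = scores, loadings = loadings,
      var_frac = 100 * var_all / sum(var_all),
      center = pc$center,
      scaled = scale.,
      n_components = min(n_components, ncol(scores))
    ),
    class = "hcp_pca"
  )
}

#' @describeIn pca_profiles Scores of the leading components as a tibble
#'   (one row per sample).
#' @exportS3Method generics::tidy
tidy.hcp_pca <- function(x, ...) {
  ix <- seq_len(x$n_components)
  tibble::as_tibble(x$scores[, ix, drop = FALSE], rownames = "sample")
}

#' @describeIn pca_profiles One-row summary with the variance fractions of
#'   the leading components.
#' @exportS3Method generics::glance
glance.hcp_pca <- function(x, ...) {
  ix <- seq_len(x$n_components)
  out <- tibble::as_tibble(as.list(setNames(
    x$var_frac[ix], paste0("var_pct_PC", ix)
  )))
  out$n_samples <- nrow(x$scores)
  out$n_proteins <- nrow(x$loadings)
  out
}

#' Joint biplot of sample scores and protein loadings
#'
#' @param object An `hcp_pca`.
#' @param sizes Optional numeric vector (one per sample) controlling circle
#'   areas, e.g. known or predicted impurity fractions.
#' @param loading_scale Multiplier applied to loadings for display.
#' @param ... Ignored.
#' @return A ggplot biplot of the first two components: samples as circles,
#'   proteins as crosses, axes annotated with variance coverage.
#' @exportS3Method ggplot2::autoplot
autoplot.hcp_pca <- function(object, sizes = NULL, loading_scale = NULL, ...) {
  sc <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE], rownames = "label")
  names(sc)[2:3] <- c("d1", "d2")
  ld <- tibble::as_tibble(object$loadings[, 1:2, drop = FALSE], rownames = "label")
  names(ld)[2:3] <- c("d1", "d2")
  loading_scale <- loading_scale %||%
    (max(abs(c(sc$d1, sc$d2))) / max(abs(c(ld$d1, ld$d2))) * 0.8)
  ld$d1 <- ld$d1 * loading_scale
  ld$d2 <- ld$d2 * loading_scale
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$d1, y = .data$d2))
  p <- if (!is.null(sizes)) {
    p + ggplot2::geom_point(ggplot2::aes(size = sizes), shape = 21) +
      ggplot2::scale_size_area()
  } else {
    p + ggplot2::geom_point(shape = 21, size = 3)
  }
  p +
    ggplot2::geom_point(data = ld, shape = 4, colour = "grey40") +
    ggplot2::labs(
      x = sprintf("PC 1 (%.1f%%)", object$var_frac[1]),
      y = sprintf("PC 2 (%.1f%%)", object$var_frac[2])
    ) +
    ggplot2::theme_minimal()
}

#' Top-N capture fraction of the host signal
#'
#' Ranks host proteins by descending MS1 intensity and reports which fraction
#' of the total host signal the N most abundant capture. Ties are broken by
#' lexicographic accession order so the ranking is deterministic.
#'
#' @param table An intensity-table tibble.
#' @param groups A group assignment.
#' @param run_id Run column used for the capture computation.
#' @param n Number of top proteins.
#' @param rank_by `"run"` (default) ranks by intensity in `run_id`; `"mean"`
#'   ranks by the cross-run mean intensity (missing treated as 0).
#' @return A one-row tibble: `run_id`, `n`, `capture` (fraction of host
#'   signal), `n_host`, and list-column `top_accessions`. When `n` exceeds
#'   the number of host proteins the capture is 1 and a note is attached.
#' @export
top_n_capture <- function(table, groups, run_id, n, rank_by = c("run", "mean")) {
  rank_by <- match.arg(rank_by)
  table <- validate_intensity_table(table)
  if (n < 1) abort("n must be >= 1", class = "hcp_domain_error")
  g <- groups$group[match(table$accession, groups$accession)]
  host <- table[g == "host", , drop = FALSE]
  if (nrow(host) == 0 || !run_id %in% intensity_runs(table)) {
    abort("no host proteins or unknown run", class = "hcp_validation_error")
  }
  v <- host[[run_id]]
  v[is.na(v)] <- 0
  key <- if (rank_by == "run") v else rowMeans(replace(as.matrix(host[intensity_runs(host)]), is.na(as.matrix(host[intensity_runs(host)])), 0))
  ord <- order(-key, host$accession)
  note <- NA_character_
  if (n >= nrow(host)) {
    if (n > nrow(host)) note <- "n exceeds number of host proteins; capture = 1"
    n <- nrow(host)
  }
  top <- ord[seq_len(n)]
  tibble::tibble(
    run_id = run_id, n = n,
    capture = sum(v[top]) / sum(v),
    n_host = nrow(host),
    top_accessions = list(host$accession[top]),
    note = note
  )
}

#' Systematic bias of a top-N quantification strategy
#'
#' Quantifying only the N most abundant host proteins captures a fraction of
#' the true host signal; the resulting impurity estimate is low by exactly
#' the uncaptured share, and the material purity is overestimated. Given the
#' true impurity mass fraction and the capture fraction, reports the biased
#' impurity estimate, the relative impurity error, and the purity bias in
#' mg/g and percentage points.
#'
#' @param w_imp True impurity mass fraction, mg/g.
#' @param capture Capture fraction in `(0, 1]` (from [top_n_capture()]).
#' @return A tibble (vectorized): `w_imp`, `capture`, `w_est`
#'   (= capture * w_imp), `rel_impurity_error_pct` (= (1 - capture) * 100),
#'   `purity_true`, `purity_est`, `purity_bias` (mg/g, >= 0) and
#'   `purity_bias_pct` (percentage points on the g/g scale).
#' @export
capture_bias <- function(w_imp, capture) {
  if (any(!is.finite(capture)) || any(capture <= 0) || any(capture > 1)) {
    abort("capture must lie in (0, 1]", class = "hcp_domain_error")
  }
  if (any(!is.finite(w_imp)) || any(w_imp < 0)) {
    abort("w_imp must be >= 0", class = "hcp_domain_error")
  }
  n <- max(length(w_imp), length(capture))
  w_imp <- rep_len(w_imp, n)
  capture <- rep_len(capture, n)
  w_est <- capture * w_imp
  p_true <- impurity_to_purity(w_imp, 0)$purity
  p_est <- impurity_to_purity(w_est, 0)$purity
  tibble::tibble(
    w_imp = w_imp, capture = capture, w_est = w_est,
    rel_impurity_error_pct = (1 - capture) * 100,
    purity_true = p_true, purity_est = p_est,
    purity_bias = p_est - p_true,
    purity_bias_pct = (p_est - p_true) / 10
  )
}
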