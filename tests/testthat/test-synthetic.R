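# Runs the pipeline end to end on generated data: these tests validate both
# the generator's statistical structure and the estimator built on top of it.

pipeline_predict <- function(ds) {
  pts <- dplyr::inner_join(
    tibble::as_tibble(ds$design),
    compute_ratios(ds$calibration, ds$groups, ds$design$run_id),
    by = "run_id"
  )
  fit <- fit_calibration(pts)
  predict_mass_fraction(fit, compute_ratios(ds$sample, ds$groups)$R)
}

test_that("identical seeds give bit-identical datasets", {
  s <- synthetic_spec(K_host = 12, seed = 71)
  d1 <- generate_dataset(s)
  d2 <- generate_dataset(s)
  expect_identical(d1$calibration, d2$calibration)
  expect_identical(d1$sample, d2$sample)
  expect_identical(d1$truth$r_host, d2$truth$r_host)
  d3 <- generate_dataset(synthetic_spec(K_host = 12, seed = 72))
  expect_false(identical(d1$calibration, d3$calibration))
})

test_that("the deterministic limit is an exact line with the analytic slope", {
  ds <- generate_dataset(synthetic_spec(
    K_host = 8, response_cv = 0, noise_cv = 0, seed = 73
  ))
  pts <- dplyr::inner_join(
    tibble::as_tibble(ds$design),
    compute_ratios(ds$calibration, ds$groups, ds$design$run_id),
    by = "run_id"
  )
  # equal mean response factors: intensity ratio equals mass ratio, slope
  # 1/1000 per mg/g
  expect_equal(pts$R, pts$w_known / 1000, tolerance = 1e-12)
  fit <- fit_calibration(pts)
  expect_equal(fit$b, ds$truth$slope, tolerance = 1e-10)
  expect_equal(fit$b, 1 / 1000, tolerance = 1e-10)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  pred <- pipeline_predict(ds)
  expect_equal(pred$w0, ds$truth$w_true, tolerance = 1e-9)
})

test_that("with heterogeneous response factors the fitted slope tracks the truth", {
  ds <- generate_dataset(synthetic_spec(
    K_host = 30, response_cv = 0.3, noise_cv = 0.02, seed = 74
  ))
  fit <- fit_calibration(dplyr::inner_join(
    tibble::as_tibble(ds$design),
    compute_ratios(ds$calibration, ds$groups, ds$design$run_id),
    by = "run_id"
  ))
  expect_equal(fit$b, ds$truth$slope, tolerance = 0.05)
})

test_that("intensity-ratio-equals-mass-ratio holds in expectation across proteomes", {
  # many equal-share proteins on both sides: the fitted slope concentrates
  # around 1/1000 per mg/g even with 30 % response-factor spread
  slopes <- vapply(1:50, function(i) {
    ds <- generate_dataset(synthetic_spec(
      K_host = 80, host_shares = rep(1 / 80, 80),
      K_target = 40, target_shares = rep(1 / 40, 40),
      response_cv = 0.3, noise_cv = 0.02,
      sample_runs = 1, seed = 700 + i
    ))
    fit_calibration(dplyr::inner_join(
      tibble::as_tibble(ds$design),
      compute_ratios(ds$calibration, ds$groups, ds$design$run_id),
      by = "run_id"
    ))$b
  }, numeric(1))
  expect_equal(mean(slopes), 1 / 1000, tolerance = 0.03)
})

test_that("parameter recovery: bias, uncertainty realism and coverage", {
  reps <- 500
  res <- purrr::map_dfr(seq_len(reps), function(i) {
    ds <- generate_dataset(synthetic_spec(
      K_host = 20, response_cv = 0.3, noise_cv = 0.05,
      levels = c(22.7, 47.4, 69.9, 92.8, 117.1, 140.8), replicates = 3,
      w_true = 84, sample_runs = 3, seed = 8000 + i
    ))
    pipeline_predict(ds)
  })
  rel_bias <- (res$w0 - 84) / 84
  expect_lt(abs(median(rel_bias)) * 100, 1)
  # the inverse-prediction formula tracks the empirical scatter within 2x
  expect_lt(sd(res$w0), 2 * mean(res$s_x0))
  expect_gt(sd(res$w0), mean(res$s_x0) / 2)
  # 3-sigma coverage of the truth
  covered <- abs(res$w0 - 84) <= 3 * res$s_x0
  expect_gte(mean(covered), 0.95)
})

test_that("calibrant proteomes drawn from one response distribution are commutable", {
  # same target stock (fixed response), two independent calibrant proteomes;
  # the fixed sample is predicted consistently by either calibration
  mk <- function(seed) {
    generate_dataset(synthetic_spec(
      K_host = 100, host_shares = rep(0.01, 100),
      response_cv = 0.15, target_response_cv = 0, noise_cv = 0.05,
      sample_runs = 3, seed = seed
    ))
  }
  a <- mk(81)
  b <- mk(82)
  fit_of <- function(ds) {
    fit_calibration(dplyr::inner_join(
      tibble::as_tibble(ds$design),
      compute_ratios(ds$calibration, ds$groups, ds$design$run_id),
      by = "run_id"
    ))
  }
  fa <- fit_of(a)
  fb <- fit_of(b)
  y_sample <- compute_ratios(a$sample, a$groups)$R
  wa <- predict_mass_fraction(fa, y_sample)$w0
  wb <- predict_mass_fraction(fb, y_sample)$w0
  band <- max(
    loo_cv(fa$points)$median_abs_error,
    loo_cv(fb$points)$median_abs_error
  )
  expect_lt(abs(wa - wb) / wa * 100, 2 * band)
})

test_that("an optional detection floor produces missing cells, not zeros", {
  ds <- generate_dataset(synthetic_spec(
    K_host = 40, host_share_sigma = 2, noise_cv = 0.05,
    detection_floor = 5e4, seed = 75
  ))
  vals <- as.matrix(ds$calibration[intensity_runs(ds$calibration)])
  expect_gt(sum(is.na(vals)), 0)
  expect_true(all(vals >= 5e4, na.rm = TRUE))
  # the ratio pipeline still runs on tables with dropout
  expect_s3_class(compute_ratios(ds$calibration, ds$groups), "tbl_df")
})

test_that("the nine-protein mix fixture matches its declared design", {
  fx <- make_mix_fixture()
  expect_equal(sum(fx$mass_shares), 1, tolerance = 1e-12)
  expect_equal(length(fx$mass_shares), 9L)
  expect_equal(
    unname(fx$mass_shares),
    c(0.1055, 0.1176, 0.124, 0.1251, 0.1247, 0.0317, 0.1215, 0.126, 0.1233) / 0.9994,
    tolerance = 1e-12
  )
  expect_equal(sort(unique(fx$broad$design$w_known)),
    c(22.7, 47.4, 69.9, 92.8, 117.1, 140.8))
  expect_equal(nrow(fx$broad$design), 18L)
  expect_equal(sort(unique(fx$low$design$w_known)),
    c(0.2, 0.3, 0.4, 0.7, 1.1, 1.4))
  expect_equal(nrow(fx$low$design), 12L)
  host <- fx$broad$groups$accession[fx$broad$groups$group == "host"]
  expect_setequal(host, names(fx$mass_shares))

  # the fixture round-trips through the text representation exactly
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(fx$broad$calibration, path)
  back <- read_intensity_table(path)
  expect_equal(as.matrix(back[-1]), as.matrix(fx$broad$calibration[-1]),
    tolerance = 1e-12
  )
  expect_identical(back$accession, fx$broad$calibration$accession)
})

test_that("invalid generator settings are rejected", {
  expect_error(synthetic_spec(), class = "hcp_validation_error")
  expect_error(synthetic_spec(K_host = 0, seed = 1), class = "hcp_validation_error")
  expect_error(synthetic_spec(noise_cv = -1, seed = 1), class = "hcp_validation_error")
})
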