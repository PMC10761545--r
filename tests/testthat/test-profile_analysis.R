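make_profile_fixture <- function() {
  # four watchlist proteins carry 65 % of host signal in run1
  tbl <- tibble::tibble(
    accession = c("P77398", "P76344", "P17169", "P23908", "H5", "H6", "T1"),
    run1 = c(30, 15, 12, 8, 20, 15, 200),
    run2 = c(10, 10, 10, 10, 5, 5, 100)
  )
  g <- assign_groups(tbl,
    target_ids = "T1",
    host_ids = c("P77398", "P76344", "P17169", "P23908", "H5", "H6")
  )
  list(tbl = tbl, g = g)
}

test_that("co-purified fraction is the watchlist share of host signal", {
  fx <- make_profile_fixture()
  watch <- c("P77398", "P76344", "P17169", "P23908")
  f <- copurified_fraction(fx$tbl, fx$g, watch, "run1")
  expect_equal(f$fraction, 65 / 100)
  # watchlist covering the whole host group
  all_host <- fx$g$accession[fx$g$group == "host"]
  expect_equal(copurified_fraction(fx$tbl, fx$g, all_host, "run1")$fraction, 1)
  # empty watchlist
  expect_equal(copurified_fraction(fx$tbl, fx$g, character(0), "run1")$fraction, 0)
})

test_that("co-purified fraction flags zero-host runs and ignores run scale", {
  fx <- make_profile_fixture()
  watch <- c("P77398", "P76344")
  f1 <- copurified_fraction(fx$tbl, fx$g, watch, "run1")$fraction
  scaled <- dplyr::mutate(fx$tbl, run1 = run1 * 1e3)
  expect_equal(copurified_fraction(scaled, fx$g, watch, "run1")$fraction, f1)

  zero <- dplyr::mutate(fx$tbl, run1 = ifelse(accession == "T1", 100, 0))
  expect_warning(fz <- copurified_fraction(zero, fx$g, watch, "run1"), "zero host")
  expect_true(is.na(fz$fraction))
  expect_false(fz$defined)
})

test_that("the profile matrix fills missing identifications with zero", {
  tbl <- tibble::tibble(
    accession = c("H1", "H2", "T1"),
    run1 = c(10, NA, 100), run2 = c(20, 5, 90)
  )
  g <- assign_groups(tbl, target_ids = "T1", host_ids = c("H1", "H2"))
  m <- profile_matrix(tbl, g)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["run1", "H2"], 0)
  expect_equal(m["run2", "H2"], 5)
})

test_that("a rank-1 profile collapses on one component aligned with its protein", {
  m <- cbind(A = c(1, 2, 3, 4), B = rep(5, 4), C = rep(2, 4))
  pc <- pca_profiles(m)
  expect_equal(pc$var_frac[1], 100, tolerance = 1e-9)
  expect_equal(abs(pc$loadings["A", 1]), 1, tolerance = 1e-9)
  # sign convention: the dominant loading is positive
  expect_gt(pc$loadings["A", 1], 0)
})

test_that("scores and loadings reconstruct the centered matrix", {
  set.seed(41)
  m <- matrix(stats::rexp(6 * 20, rate = 1e-6), nrow = 6)
  colnames(m) <- paste0("P", 1:20)
  pc <- pca_profiles(m)
  recon <- pc$scores %*% t(pc$loadings) + matrix(pc$center,
    nrow = nrow(m), ncol = ncol(m), byrow = TRUE
  )
  expect_equal(unname(recon), unname(m), tolerance = 1e-8)
  expect_equal(sum(pc$var_frac), 100, tolerance = 1e-9)
  expect_true(all(diff(pc$var_frac) <= 1e-9))
})

test_that("two orthogonal dilution series separate in the score plane", {
  # series A dilutes proteins P1-P3, series B dilutes P4-P6
  lev <- c(1, 2, 4, 8)
  a_block <- outer(lev, c(5, 3, 2))
  b_block <- outer(lev, c(4, 4, 1))
  m <- rbind(
    cbind(a_block, matrix(0.01, 4, 3)),
    cbind(matrix(0.01, 4, 3), b_block)
  )
  colnames(m) <- paste0("P", 1:6)
  rownames(m) <- c(paste0("A", 1:4), paste0("B", 1:4))
  pc <- pca_profiles(m)
  expect_gt(pc$var_frac[1] + pc$var_frac[2], 99.9)
  # each series varies along its own direction in the score plane, and the
  # two directions stay orthogonal (the blocks are orthogonal in data space)
  a_rows <- paste0("A", 1:4)
  b_rows <- paste0("B", 1:4)
  dir_a <- pc$scores[a_rows[4], 1:2] - pc$scores[a_rows[1], 1:2]
  dir_b <- pc$scores[b_rows[4], 1:2] - pc$scores[b_rows[1], 1:2]
  cosang <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_lt(abs(cosang(dir_a, dir_b)), 0.05)
  # each series' dominant proteins point along that series in the biplot
  expect_gt(abs(cosang(pc$loadings["P1", 1:2], dir_a)), 0.95)
  expect_gt(abs(cosang(pc$loadings["P4", 1:2], dir_b)), 0.95)
  expect_lt(abs(cosang(pc$loadings["P1", 1:2], dir_b)), 0.3)
})

test_that("the default decomposition is unscaled (guard against silent scaling)", {
  set.seed(42)
  m <- cbind(
    big = stats::rnorm(8, 1e6, 2e5),
    small = stats::rnorm(8, 10, 2)
  )
  raw <- pca_profiles(m)
  scl <- pca_profiles(m, scale. = TRUE)
  # unscaled: the high-variance column dominates PC1 almost alone
  expect_gt(abs(raw$loadings["big", 1]), 0.999)
  # unit-variance scaling must change the loadings on this anisotropic input
  expect_false(isTRUE(all.equal(abs(raw$loadings[, 1]), abs(scl$loadings[, 1]),
    tolerance = 1e-3
  )))
})

test_that("top-N capture ranks by intensity with deterministic ties", {
  tbl <- tibble::tibble(
    accession = c("H_b", "H_a", "H_c", "T1"),
    run1 = c(30, 50, 20, 100)
  )
  g <- assign_groups(tbl, target_ids = "T1", host_ids = c("H_a", "H_b", "H_c"))
  top2 <- top_n_capture(tbl, g, "run1", 2)
  expect_equal(top2$capture, 0.8)
  expect_equal(top2$top_accessions[[1]], c("H_a", "H_b"))
  expect_equal(top_n_capture(tbl, g, "run1", 3)$capture, 1.0)
  over <- top_n_capture(tbl, g, "run1", 10)
  expect_equal(over$capture, 1.0)
  expect_match(over$note, "exceeds")
  # capture is monotone non-decreasing in N
  caps <- vapply(1:3, function(k) top_n_capture(tbl, g, "run1", k)$capture, numeric(1))
  expect_true(all(diff(caps) >= 0))
  # ties: equal intensities ranked lexicographically
  tie <- dplyr::mutate(tbl, run1 = c(30, 30, 30, 100))
  expect_equal(top_n_capture(tie, g, "run1", 1)$top_accessions[[1]], "H_a")
})

test_that("capture bias follows the uncaptured share and inflates purity", {
  b <- capture_bias(c(84, 78), c(0.69, 0.88))
  expect_equal(b$rel_impurity_error_pct, c(31, 12))
  expect_equal(b$w_est, c(0.69 * 84, 0.88 * 78))
  expect_true(all(b$purity_bias > 0))
  # full capture: no bias
  expect_equal(capture_bias(84, 1)$purity_bias, 0)
  # bias grows strictly with the uncaptured share for fixed impurity
  biases <- capture_bias(rep(84, 4), c(0.9, 0.7, 0.5, 0.3))$purity_bias
  expect_true(all(diff(biases) > 0))
  expect_error(capture_bias(84, 0), class = "hcp_domain_error")
})
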