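#' Specification for a synthetic LFQ dataset
#'
#' Describes a simulated spike-in experiment at protein-level resolution.
#' Each protein j carries a fixed multiplicative MS1 response factor r_j
#' (intensity per unit mass, lognormal across proteins with relative spread
#' `response_cv`); the intensity of protein j in run k is
#' `r_j * m_jk * eps_jk`, where `m_jk` is the protein mass implied by the
#' design level and the protein's mass share, and `eps_jk` is multiplicative
#' lognormal replicate noise with relative spread `noise_cv`. Response
#' factors are drawn once per protein and held fixed across runs, so the
#' heterogeneity that limits label-free quantification is between proteins,
#' not between runs.
#'
#' @param K_host Number of host/calibrant proteins.
#' @param K_target Number of target protein chains (default 2, mimicking the
#'   alpha and delta chains of a hemoglobin tetramer).
#' @param host_shares Explicit mass shares of the host proteins (summing to
#'   1), or `NULL` to draw them lognormal with `host_share_sigma` and
#'   normalize.
#' @param host_share_sigma Lognormal sigma of drawn host mass shares.
#' @param target_shares Mass shares of the target chains.
#' @param response_cv Between-protein coefficient of variation of the MS1
#'   response factor (default 0.30).
#' @param target_response_cv Response-factor CV of the target chains; default
#'   equal to `response_cv`. Set to 0 to emulate a shared target stock across
#'   calibrant sources (commutability studies).
#' @param noise_cv Replicate-noise coefficient of variation per
#'   (protein, run) (default 0.05).
#' @param levels Known calibrant mass fractions of the dilution series
#'   (mg calibrant protein / g target protein). Default: a bacterial-lysate
#'   spike series of 10.3, 25.0, 52.7, 80.1 and 111.6 mg/g.
#' @param replicates LC-MS runs per calibration level (default 3).
#' @param w_true True impurity mass fraction of the simulated sample, mg/g.
#' @param sample_runs Number of sample measurement runs (default 6).
#' @param intensity_scale Overall intensity scale (arbitrary units); cancels
#'   in every ratio.
#' @param detection_floor Intensity below which a protein is reported as
#'   missing in that run, or `NULL` (default) for no dropout.
#' @param U_cal_rel Expanded (95 %) relative uncertainty assigned to the
#'   calibrant stock, percent.
#' @param source_label Calibrant name recorded in the design.
#' @param seed Mandatory integer seed.
#' @return A list of class `hcp_synth_spec`.
#' @seealso [generate_dataset()], [make_mix_fixture()]
#' @export
synthetic_spec <- function(K_host = 50,
                           K_target = 2,
                           host_shares = NULL,
                           host_share_sigma = 1,
                           target_shares = c(0.5, 0.5),
                           response_cv = 0.30,
                           target_response_cv = response_cv,
                           noise_cv = 0.05,
                           levels = c(10.3, 25.0, 52.7, 80.1, 111.6),
                           replicates = 3,
                           w_true = 84,
                           sample_runs = 6,
                           intensity_scale = 1e9,
                           detection_floor = NULL,
                           U_cal_rel = 3.5,
                           source_label = "synthetic lysate",
                           seed) {
  if (missing(seed)) abort("seed is mandatory", class = "hcp_validation_error")
  if (K_host < 1 || K_target < 1) {
    abort("need at least one host and one target protein", class = "hcp_validation_error")
  }
  if (response_cv < 0 || noise_cv < 0) {
    abort("coefficients of variation must be >= 0", class = "hcp_validation_error")
  }
  if (!is.null(host_shares)) {
    stopifnot(length(host_shares) == K_host, all(host_shares > 0))
    host_shares <- host_shares / sum(host_shares)
  }
  stopifnot(length(target_shares) == K_target, all(target_shares > 0))
  structure(
    list(
      K_host = K_host, K_target = K_target,
      host_shares = host_shares, host_share_sigma = host_share_sigma,
      target_shares = target_shares / sum(target_shares),
      response_cv = response_cv, target_response_cv = target_response_cv,
      noise_cv = noise_cv,
      levels = levels, replicates = replicates,
      w_true = w_true, sample_runs = sample_runs,
      intensity_scale = intensity_scale,
      detection_floor = detection_floor,
      U_cal_rel = U_cal_rel, source_label = source_label,
      seed = as.integer(seed)
    ),
    class = "hcp_synth_spec"
  )
}

# lognormal with mean 1 and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic LFQ dataset
#'
#' Simulates the full spike-in experiment described by a [synthetic_spec()]:
#' a calibration intensity table (one run column per level x replicate), the
#' matching calibrator design, a sample intensity table measured at the true
#' impurity mass fraction, and a truth record holding every latent variable
#' (mass shares, response factors, the analytic slope) for parameter-recovery
#' tests. The target protein mass per run is fixed at 1 g (arbitrary), so a
#' design level w puts `w / 1000 * share_j` g of host protein j in the run.
#' Identical seeds give bit-identical datasets.
#'
#' @param spec An `hcp_synth_spec`.
#' @return A list: `calibration` (intensity table), `design` (`hcp_design`
#'   with per-protein `mass_shares`), `sample` (intensity table),
#'   `sample_run_ids`, `groups` (target/host assignment), `truth` (list).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "hcp_synth_spec"))
  set.seed(spec$seed)
  host_acc <- sprintf("HOST%04d", seq_len(spec$K_host))
  target_acc <- sprintf("TGT%02d", seq_len(spec$K_target))
  shares <- spec$host_shares %||% {
    raw <- stats::rlnorm(spec$K_host, 0, spec$host_share_sigma)
    raw / sum(raw)
  }
  r_host <- rlnorm_cv(spec$K_host, spec$response_cv)
  r_target <- rlnorm_cv(spec$K_target, spec$target_response_cv)

  cal_runs <- as.vector(t(outer(
    seq_along(spec$levels), seq_len(spec$replicates),
    function(l, r) sprintf("cal_L%d_r%d", l, r)
  )))
  cal_w <- rep(spec$levels, each = spec$replicates)
  smp_runs <- sprintf("sample_r%d", seq_len(spec$sample_runs))

  run_intensities <- function(w) {
    m_host <- w / 1000 * shares
    m_target <- spec$target_shares
    mu <- c(r_host * m_host, r_target * m_target) * spec$intensity_scale
    v <- mu * rlnorm_cv(length(mu), spec$noise_cv)
    if (!is.null(spec$detection_floor)) v[v < spec$detection_floor] <- NA_real_
    v
  }

  cal_mat <- vapply(cal_w, run_intensities, numeric(spec$K_host + spec$K_target))
  smp_mat <- vapply(
    rep(spec$w_true, spec$sample_runs), run_intensities,
    numeric(spec$K_host + spec$K_target)
  )
  accessions <- c(host_acc, target_acc)
  as_table <- function(mat, runs) {
    tbl <- tibble::as_tibble(as.data.frame(mat))
    names(tbl) <- runs
    dplyr::bind_cols(tibble::tibble(accession = accessions), tbl)
  }
  design <- calibrator_design(
    level_id = sprintf("L%d", rep(seq_along(spec$levels), each = spec$replicates)),
    w_known = cal_w, run_id = cal_runs,
    U_cal_rel = spec$U_cal_rel, source_label = spec$source_label,
    mass_shares = setNames(shares, host_acc)
  )
  groups <- tibble::tibble(
    accession = accessions,
    group = c(rep("host", spec$K_host), rep("target", spec$K_target))
  )
  slope_true <- sum(r_host * shares) / sum(r_target * spec$target_shares) / 1000
  list(
    calibration = as_table(cal_mat, cal_runs),
    design = design,
    sample = as_table(smp_mat, smp_runs),
    sample_run_ids = smp_runs,
    groups = groups,
    truth = list(
      spec = spec, host_shares = setNames(shares, host_acc),
      r_host = setNames(r_host, host_acc),
      r_target = setNames(r_target, target_acc),
      slope = slope_true, w_true = spec$w_true
    )
  )
}

#' Nine-protein calibrant mix fixture
#'
#' A fully synthetic stand-in for a defined nine-protein calibrant mix: the
#' proteins carry the gravimetric mass ratio
#' 0.1055 : 0.1176 : 0.124 : 0.1251 : 0.1247 : 0.0317 : 0.1215 : 0.1260 :
#' 0.1233 (somatotropin, ceruloplasmin, serotransferrin, beta-2
#' microglobulin, insulin, C-reactive protein, albumin, cytochrome c,
#' myoglobin), two target chains, and two dilution grids: a broad range of
#' 22.7, 47.4, 69.9, 92.8, 117.1 and 140.8 mg/g measured in triplicate
#' (n = 18 calibration runs, df = 16), and a low range of 0.2, 0.3, 0.4,
#' 0.7, 1.1 and 1.4 mg/g measured in duplicate (n = 12, df = 10) for
#' low-level impurity work. The broad-range sample is simulated at
#' `w_true = 84` mg/g with six measurement runs; the low-range sample at
#' 0.86 mg/g with one. Intensities are simulated, not measured; the fixture
#' exists so that calibration, cross-validation and protein-subsampling code
#' can be exercised end to end.
#'
#' @param seed Integer seed (default 20230) controlling all random draws.
#' @param response_cv Between-protein response-factor CV (default 0.30).
#' @param noise_cv Replicate-noise CV (default 0.05).
#' @return A list with elements `broad` and `low`, each a
#'   [generate_dataset()] bundle, plus `mass_shares` (the normalized mix
#'   ratio) and `seed`.
#' @export
make_mix_fixture <- function(seed = 20230, response_cv = 0.30, noise_cv = 0.05) {
  ratio <- c(
    somatotropin = 0.1055, ceruloplasmin = 0.1176, serotransferrin = 0.124,
    b2microglobulin = 0.1251, insulin = 0.1247, c_reactive_protein = 0.0317,
    albumin = 0.1215, cytochrome_c = 0.1260, myoglobin = 0.1233
  )
  shares <- ratio / sum(ratio)
  broad <- generate_dataset(synthetic_spec(
    K_host = 9, host_shares = unname(shares),
    response_cv = response_cv, noise_cv = noise_cv,
    levels = c(22.7, 47.4, 69.9, 92.8, 117.1, 140.8), replicates = 3,
    w_true = 84, sample_runs = 6,
    U_cal_rel = 3.2, source_label = "protein mix",
    seed = seed
  ))
  low <- generate_dataset(synthetic_spec(
    K_host = 9, host_shares = unname(shares),
    response_cv = response_cv, noise_cv = noise_cv,
    levels = c(0.2, 0.3, 0.4, 0.7, 1.1, 1.4), replicates = 2,
    w_true = 0.86, sample_runs = 1,
    U_cal_rel = 3.2, source_label = "protein mix (low range)",
    seed = seed + 1L
  ))
  # carry the mix accession names into the tables
  rename_hosts <- function(bundle) {
    map <- setNames(names(shares), sprintf("HOST%04d", seq_along(shares)))
    for (el in c("calibration", "sample")) {
      bundle[[el]]$accession <- dplyr::coalesce(
        unname(map[bundle[[el]]$accession]), bundle[[el]]$accession
      )
    }
    bundle$groups$accession <- dplyr::coalesce(
      unname(map[bundle$groups$accession]), bundle$groups$accession
    )
    ms <- attr(bundle$design, "mass_shares")
    names(ms) <- unname(map[names(ms)])
    attr(bundle$design, "mass_shares") <- ms
    names(bundle$truth$host_shares) <- unname(map[names(bundle$truth$host_shares)])
    names(bundle$truth$r_host) <- unname(map[names(bundle$truth$r_host)])
    bundle
  }
  list(
    broad = rename_hosts(broad), low = rename_hosts(low),
    mass_shares = shares, seed = seed
  )
}
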