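#' Unimodal taxon-climate response curves
#'
#' Each synthetic taxon responds to July temperature and annual water balance
#' through a product of two Gaussian curves: optimum, tolerance (Gaussian sd)
#' and peak abundance per variable. The product surface is normalized across
#' taxa to an expected pollen composition, from which counted assemblages are
#' drawn multinomially.
#'
#' @param taxon_name Character labels.
#' @param opt_tjul,tol_tjul Optimum and tolerance in July temperature
#'   (degrees C; tolerance > 0).
#' @param opt_wb,tol_wb Optimum and tolerance in annual water balance (mm/a).
#' @param peak_abundance Height of the response surface at the optimum,
#'   in (0, 1].
#' @return Tibble of taxon responses, one row per taxon.
#' @export
taxon_responses <- function(taxon_name, opt_tjul, tol_tjul, opt_wb, tol_wb,
                            peak_abundance = 1) {
  out <- tibble(
    taxon_name = as.character(taxon_name),
    opt_tjul = opt_tjul, tol_tjul = tol_tjul,
    opt_wb = opt_wb, tol_wb = tol_wb,
    peak_abundance = peak_abundance
  )
  if (any(out$tol_tjul <= 0) || any(out$tol_wb <= 0)) abort("Tolerances must be positive.")
  if (any(out$peak_abundance <= 0) || any(out$peak_abundance > 1)) {
    abort("`peak_abundance` must be in (0, 1].")
  }
  if (anyDuplicated(out$taxon_name)) abort("Taxon names must be unique.")
  out
}

#' Default synthetic pollen taxonomy
#'
#' Eight taxa spanning the moisture and temperature gradients of eastern
#' North American pollen floras: dry-prairie forbs (`sagebrush_like`,
#' `amaranth_like`) as moisture indicators, a summer-temperature indicator
#' tree (`oak_like`), and trees/graminoids of intermediate to moist, cool
#' settings. Moisture indicators have narrow water-balance but broad
#' temperature tolerances, and vice versa for the temperature indicator, so
#' transfer-function importance analyses separate the two signals.
#'
#' @return A taxon-response tibble (see [taxon_responses()]).
#' @export
default_taxa <- function() {
  taxon_responses(
    taxon_name = c("sagebrush_like", "amaranth_like", "oak_like", "pine_like",
                   "birch_like", "fir_like", "grass_like", "sedge_like"),
    opt_tjul = c(16, 17, 20, 14, 12, 10, 18, 11),
    tol_tjul = c(8, 8, 2.5, 6, 5, 4, 7, 6),
    opt_wb = c(-320, -220, 420, 120, 620, 850, -80, 320),
    tol_wb = c(240, 210, 700, 420, 320, 320, 340, 520),
    peak_abundance = c(0.9, 0.7, 1.0, 1.0, 0.8, 0.6, 0.5, 0.4)
  )
}

# expected composition at (tjul, wb): normalized product-Gaussian responses
expected_composition <- function(tjul, wb, taxa) {
  s <- vapply(seq_len(nrow(taxa)), function(j) {
    taxa$peak_abundance[j] *
      exp(-0.5 * ((tjul - taxa$opt_tjul[j]) / taxa$tol_tjul[j])^2) *
      exp(-0.5 * ((wb - taxa$opt_wb[j]) / taxa$tol_wb[j])^2)
  }, numeric(length(tjul)))
  if (length(tjul) == 1L) s <- matrix(s, nrow = 1L)
  sweep(s, 1, rowSums(s), "/")
}

count_assemblages <- function(expected, pollen_count) {
  m <- apply(expected, 1, function(p) {
    as.numeric(rmultinom(1, pollen_count, p)) / pollen_count
  })
  if (is.null(dim(m))) matrix(m, ncol = 1L) else t(m)
}

#' Generate a synthetic pollen-climate calibration dataset
#'
#' Site climates are drawn from a Gaussian copula with uniform marginals over
#' the stated ranges, targeting a (low) Pearson correlation between July
#' temperature and water balance, mirroring the near-orthogonal gradients of
#' the real eastern North American calibration data (r = -0.11). Expected
#' compositions follow the taxon response surfaces; observed compositions are
#' multinomial counts of `pollen_count` grains. Synthetic coordinates place
#' the temperature gradient north-south and the moisture gradient east-west.
#'
#' @param n_sites Number of surface samples (>= 2).
#' @param taxa Taxon-response tibble (default [default_taxa()]).
#' @param tjul_range,wb_range Climate ranges (low < high); the water-balance
#'   default matches the -348 to 1343 mm/a calibration span.
#' @param climate_correlation Target Pearson correlation between the two
#'   climate variables across sites (|r| < 1).
#' @param pollen_count Grains counted per sample.
#' @param seed Integer seed for bit-reproducibility.
#' @return A calibration tibble (see [as_calibration()]) with `site_id`,
#'   `lat`, `lon`, taxon proportion columns, `tjul`, `water_balance`, `gdd5`.
#' @export
generate_calibration_dataset <- function(n_sites, taxa = default_taxa(),
                                         tjul_range = c(8, 22),
                                         wb_range = c(-348, 1343),
                                         climate_correlation = -0.11,
                                         pollen_count = 400,
                                         seed = NULL) {
  check_number(n_sites, "n_sites", lower = 2)
  if (!nrow(taxa)) abort("`taxa` must be nonempty.")
  if (diff(tjul_range) <= 0) abort("`tjul_range` must have low < high.")
  if (diff(wb_range) <= 0) abort("`wb_range` must have low < high.")
  check_number(climate_correlation, "climate_correlation", lower = -1, upper = 1)
  if (abs(climate_correlation) >= 1) abort("|climate_correlation| must be < 1.")
  check_number(pollen_count, "pollen_count", lower = 1)

  with_seed(seed, {
    z1 <- rnorm(n_sites)
    z2 <- climate_correlation * z1 + sqrt(1 - climate_correlation^2) * rnorm(n_sites)
    u1 <- stats::pnorm(z1)
    u2 <- stats::pnorm(z2)
    tjul <- tjul_range[1] + u1 * diff(tjul_range)
    wb <- wb_range[1] + u2 * diff(wb_range)
    comp <- count_assemblages(expected_composition(tjul, wb, taxa), pollen_count)
    colnames(comp) <- taxa$taxon_name
    # plausible monthly cycle around tjul for a GDD5 target
    gdd <- gdd5(outer(tjul - 14, rep(1, 12)) + 14 +
                  outer(rep(1, n_sites), -12 * cos(2 * pi * (1:12) / 12)))
    out <- dplyr::bind_cols(
      tibble(
        site_id = sprintf("cal%04d", seq_len(n_sites)),
        lat = 50 - 12 * (tjul - tjul_range[1]) / diff(tjul_range) + rnorm(n_sites, 0, 0.5),
        lon = -100 + 30 * (wb - wb_range[1]) / diff(wb_range) + rnorm(n_sites, 0, 0.5)
      ),
      as_tibble(comp),
      tibble(tjul = tjul, water_balance = wb, gdd5 = gdd)
    )
    as_calibration(out, taxa$taxon_name)
  })
}

#' Ground-truth climate trajectories
#'
#' `climate_trajectory()` validates an explicit trajectory; `drought_trajectory()`
#' builds the canonical test case, a Gaussian-shaped mid-Holocene water-balance
#' excursion (e.g. a -110 mm/a drought centred at 7 ka) over a stable
#' temperature trend.
#'
#' @param age Ages in cal ka BP, strictly increasing (into the past).
#' @param tjul,wb True July temperature (degrees C) and water balance (mm/a)
#'   at each age.
#' @return Tibble `(age, tjul, wb)`.
#' @export
climate_trajectory <- function(age, tjul, wb) {
  if (length(age) < 2) abort("Trajectory needs at least 2 points.")
  if (any(diff(age) <= 0)) abort("`age` must be strictly increasing (cal ka BP).")
  if (length(tjul) != length(age) || length(wb) != length(age)) {
    abort("`age`, `tjul`, `wb` must have equal lengths.")
  }
  tibble(age = age, tjul = tjul, wb = wb)
}

#' @rdname climate_trajectory
#' @param span Age span covered, cal ka BP.
#' @param step Trajectory resolution, ka.
#' @param wb_modern Modern (age 0) water balance, mm/a.
#' @param amplitude Signed excursion amplitude, mm/a (negative = drought).
#' @param center,width Centre (ka) and Gaussian full width (ka) of the excursion.
#' @param tjul_modern,tjul_amplitude Modern July temperature and mid-Holocene
#'   warm excursion (degrees C), sharing `center` and `width`.
#' @export
drought_trajectory <- function(span = c(0, 10), step = 0.02,
                               wb_modern = 300, amplitude = -110,
                               center = 7, width = 5,
                               tjul_modern = 16, tjul_amplitude = 0.9) {
  age <- seq(span[1], span[2], by = step)
  bump <- exp(-0.5 * ((age - center) / (width / 2))^2)
  climate_trajectory(age,
                     tjul = tjul_modern + tjul_amplitude * bump,
                     wb = wb_modern + amplitude * bump)
}

#' Generate a synthetic fossil pollen sequence
#'
#' Samples are placed at irregular ages with gaps uniform in
#' `mean_spacing +/- spacing_jitter` (years), emulating the typical 60-75 yr
#' sampling of well-dated Holocene sequences. Assemblages are produced from
#' the trajectory climate through the same response model as the calibration
#' generator, so downstream reconstructions can be scored against known truth.
#'
#' @param traj Climate trajectory tibble from [climate_trajectory()].
#' @param taxa Taxon-response tibble; must match the calibration taxonomy.
#' @param mean_spacing,spacing_jitter Mean and half-range of the sample gaps,
#'   years.
#' @param pollen_count Grains counted per sample.
#' @param site_id,lat,lon,n_dates Site metadata carried into the output.
#' @param modern_wb Modern water balance recorded in the metadata; defaults to
#'   the trajectory value at its youngest age.
#' @param local_wb_sd,local_tjul_sd Standard deviation of site-local climate
#'   deviations around the regional trajectory (mm/a, degrees C); real
#'   sequences record local variability superimposed on the regional signal,
#'   and this is the between-site variance the bootstrap bands quantify.
#'   Default 0 (sites track the trajectory exactly).
#' @param local_ar1 Sample-to-sample persistence of the local deviations.
#' @param seed Integer seed.
#' @return One-row nested tibble with site metadata columns
#'   (`site_id, lat, lon, modern_wb, n_samples, n_dates, bottom_age`) and a
#'   `data` list-column holding the `(age, taxa...)` sample tibble; rows from
#'   several calls bind into a multi-site table for [filter_sites()].
#' @export
generate_fossil_sequence <- function(traj, taxa = default_taxa(),
                                     mean_spacing = 63.2, spacing_jitter = 25,
                                     pollen_count = 400,
                                     site_id = "synth01", lat = 45, lon = -90,
                                     n_dates = 10, modern_wb = NULL,
                                     local_wb_sd = 0, local_tjul_sd = 0,
                                     local_ar1 = 0.7, seed = NULL) {
  if (!all(c("age", "tjul", "wb") %in% names(traj))) {
    abort("`traj` must be a climate trajectory tibble (age, tjul, wb).")
  }
  if (nrow(traj) < 2) abort("Trajectory needs at least 2 points.")
  check_number(mean_spacing, "mean_spacing", lower = 1e-6)
  check_number(spacing_jitter, "spacing_jitter", lower = 0, upper = mean_spacing)
  with_seed(seed, {
    span_ka <- diff(range(traj$age))
    n_gaps <- ceiling(span_ka * 1000 / mean_spacing) + 1L
    gaps <- runif(n_gaps, mean_spacing - spacing_jitter, mean_spacing + spacing_jitter)
    ages <- min(traj$age) + cumsum(c(0, gaps)) / 1000
    ages <- ages[ages <= max(traj$age)]
    tj <- approx(traj$age, traj$tjul, ages)$y
    wb <- approx(traj$age, traj$wb, ages)$y
    if (local_wb_sd > 0) wb <- wb + local_deviation(length(wb), local_wb_sd, local_ar1)
    if (local_tjul_sd > 0) tj <- tj + local_deviation(length(tj), local_tjul_sd, local_ar1)
    comp <- count_assemblages(expected_composition(tj, wb, taxa), pollen_count)
    colnames(comp) <- taxa$taxon_name
    samples <- dplyr::bind_cols(tibble(age = ages), as_tibble(comp))
    tibble(
      site_id = site_id, lat = lat, lon = lon,
      modern_wb = if (is.null(modern_wb)) traj$wb[which.min(traj$age)] else modern_wb,
      n_samples = length(ages), n_dates = as.integer(n_dates),
      bottom_age = max(ages),
      data = list(samples)
    )
  })
}

# persistent site-local climate deviation, stationary AR(1) with marginal sd
local_deviation <- function(n, sd, ar1) {
  innov <- rnorm(n, 0, sd * sqrt(1 - ar1^2))
  as.numeric(stats::filter(innov, ar1, method = "recursive",
                           init = rnorm(1, 0, sd)))
}
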