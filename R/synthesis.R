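#' Site acceptance criteria for fossil sequences
#'
#' Thresholds for admitting a fossil pollen sequence to the regional
#' synthesis: enough samples and absolute datings to resolve sub-millennial
#' signals, a record reaching back at least 10 ka, and a modern water balance
#' inside the calibration range by a safety margin so that past deviations
#' remain reconstructable. The high-resolution variant applies the stricter
#' sample/dating pair used for the centennial-scale analyses.
#'
#' @param min_samples,min_dates Minimum pollen samples and absolute datings.
#' @param min_bottom_age Minimum bottom age, cal ka BP.
#' @param calib_wb_range Water-balance span of the calibration data, mm/a.
#' @param wb_margin Margin inside the calibration range, mm.
#' @param highres_min_samples,highres_min_dates Stricter thresholds applied
#'   when filtering for high-resolution sequences.
#' @return Named list of criteria.
#' @export
site_criteria <- function(min_samples = 30, min_dates = 5, min_bottom_age = 10,
                          calib_wb_range = c(-348, 1343), wb_margin = 150,
                          highres_min_samples = 125, highres_min_dates = 9) {
  out <- list(min_samples = min_samples, min_dates = min_dates,
              min_bottom_age = min_bottom_age, calib_wb_range = calib_wb_range,
              wb_margin = wb_margin, highres_min_samples = highres_min_samples,
              highres_min_dates = highres_min_dates)
  if (any(unlist(out[c("min_samples", "min_dates", "min_bottom_age", "wb_margin",
                       "highres_min_samples", "highres_min_dates")]) <= 0)) {
    abort("All thresholds must be positive.")
  }
  out
}

#' Filter fossil sequences by site criteria
#'
#' @param sites Tibble with one row per site and metadata columns
#'   `n_samples`, `n_dates`, `bottom_age`, `modern_wb` (as produced by
#'   [generate_fossil_sequence()] or [read_fossil_table()]).
#' @param criteria A [site_criteria()] list.
#' @param highres If `TRUE`, apply the stricter high-resolution sample and
#'   dating minima.
#' @return `sites` with appended logical `accepted` and character `reason`
#'   (`NA` for accepted sites; the first failing criterion otherwise).
#' @export
filter_sites <- function(sites, criteria = site_criteria(), highres = FALSE) {
  need <- c("n_samples", "n_dates", "bottom_age", "modern_wb")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols)) {
    abort(paste0("`sites` lacks metadata columns: ", paste(missing_cols, collapse = ", ")))
  }
  min_s <- if (highres) criteria$highres_min_samples else criteria$min_samples
  min_d <- if (highres) criteria$highres_min_dates else criteria$min_dates
  lo <- criteria$calib_wb_range[1] + criteria$wb_margin
  hi <- criteria$calib_wb_range[2] - criteria$wb_margin
  reason <- purrr::pmap_chr(
    sites[need],
    function(n_samples, n_dates, bottom_age, modern_wb) {
      if (any(is.na(c(n_samples, n_dates, bottom_age, modern_wb)))) return("missing_metadata")
      if (n_samples < min_s) return("too_few_samples")
      if (n_dates < min_d) return("too_few_dates")
      if (bottom_age < criteria$min_bottom_age) return("bottom_too_young")
      if (modern_wb < lo || modern_wb > hi) return("wb_outside_margin")
      NA_character_
    }
  )
  dplyr::mutate(sites, accepted = is.na(reason), reason = reason)
}

#' Reconstruct climate for filtered fossil sequences
#'
#' Applies a fitted transfer function to every sample of every sequence in a
#' nested site table, producing the long per-site reconstruction series that
#' feed [align_and_interpolate()].
#'
#' @param sites Nested site tibble with a `data` list-column of
#'   `(age, taxa...)` sample tibbles.
#' @param model A fitted `mat_model` or `brt_model`.
#' @return Long tibble `(site_id, age, value, min_analog_distance)`;
#'   `min_analog_distance` is `NA` for BRT models.
#' @export
reconstruct_sequences <- function(sites, model) {
  if (!"data" %in% names(sites)) abort("`sites` must be a nested site table with a `data` column.")
  purrr::map2_dfr(sites$site_id, sites$data, function(id, samples) {
    if (inherits(model, "mat_model")) {
      p <- mat_predict(model, samples)
      tibble(site_id = id, age = samples$age, value = p$value,
             min_analog_distance = p$min_distance)
    } else {
      tibble(site_id = id, age = samples$age,
             value = brt_predict(model, samples),
             min_analog_distance = NA_real_)
    }
  })
}

#' Align a site reconstruction to its baseline and interpolate to a 50-yr grid
#'
#' Values are expressed as deviations from the site-specific mean over the
#' baseline window (default the past 4 ka) and linearly interpolated onto a
#' uniform grid strictly inside the record span (no extrapolation).
#'
#' @param recon Tibble with `age` (cal ka BP) and `value` columns for one site.
#' @param step Grid step, ka (default 0.05 = 50 years).
#' @param baseline Baseline window `(young, old)`, cal ka BP.
#' @return Tibble `(age, anomaly)` on the uniform grid.
#' @export
align_and_interpolate <- function(recon, step = 0.05, baseline = c(0, 4)) {
  if (!all(c("age", "value") %in% names(recon))) abort("`recon` needs `age` and `value` columns.")
  if (nrow(recon) < 2) abort("Need at least 2 samples to interpolate.")
  rng <- range(recon$age)
  grid <- grid_ages(rng, step)
  if (!length(grid)) abort("Record span shorter than one grid step.")
  vals <- approx(recon$age, recon$value, xout = grid)$y
  inb <- grid >= baseline[1] & grid <= baseline[2]
  if (!any(inb)) abort("no_baseline_overlap")
  tibble(age = grid, anomaly = vals - mean(vals[inb]))
}

grid_ages <- function(rng, step) {
  lo <- ceiling(round(rng[1] / step, 9)) * step
  hi <- floor(round(rng[2] / step, 9)) * step
  if (hi < lo) return(numeric(0))
  round(seq(lo, hi, by = step), 9)
}

#' Regional bootstrap synthesis of site anomaly series
#'
#' The regional curve at each time step is the mean over the sites covering
#' that step; 95% uncertainty bands are the 2.5th and 97.5th percentiles of
#' the means over bootstrap resamples of whole sites (sequences, not
#' samples). A five-point running mean of the ensemble mean is attached.
#'
#' @param series Long tibble `(site_id, age, anomaly)` of aligned site series
#'   sharing a common grid (from [align_and_interpolate()]).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return A `regional_synthesis` tibble:
#'   `(age, mean, lower95, upper95, running_mean5, n_sites)`.
#' @export
regional_synthesis <- function(series, n_boot = 1000, seed = NULL) {
  if (!all(c("site_id", "age", "anomaly") %in% names(series))) {
    abort("`series` needs columns site_id, age, anomaly.")
  }
  if (!nrow(series)) abort("`series` is empty.")
  wide <- tidyr::pivot_wider(series, id_cols = "age", names_from = "site_id",
                             values_from = "anomaly")
  wide <- arrange(wide, .data$age)
  ages <- wide$age
  M <- as.matrix(wide[, -1, drop = FALSE])
  n_sites_step <- rowSums(!is.na(M))
  mean_curve <- rowMeans(M, na.rm = TRUE)
  mean_curve[n_sites_step == 0] <- NA_real_
  n_sites <- ncol(M)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(n_sites, n_sites, replace = TRUE)
      rowMeans(M[, pick, drop = FALSE], na.rm = TRUE)
    }, numeric(length(ages)))
  })
  if (length(ages) == 1L) boot <- matrix(boot, nrow = 1L)
  qs <- apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- tibble(
    age = ages, mean = mean_curve,
    lower95 = qs[1, ], upper95 = qs[2, ],
    running_mean5 = running_mean(mean_curve, 5),
    n_sites = n_sites_step
  )
  class(out) <- c("regional_synthesis", class(out))
  out
}

#' Centered running mean with shrinking edges
#'
#' @param x Numeric vector.
#' @param window Odd window length in points (default 5).
#' @return Smoothed vector of the same length; edge windows shrink to the
#'   available points.
#' @export
running_mean <- function(x, window = 5) {
  check_number(window, "window", lower = 1)
  if (window %% 2 == 0) abort("`window` must be odd.")
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
}

#' Centennial-scale residuals from a fixed-span LOESS trend
#'
#' Subtracts a locally weighted linear trend (tricube weights, fixed 2-ka
#' window width in time units) from a series, isolating centennial-scale
#' variability from the multi-millennial trend.
#'
#' @param data Tibble with `age` and a value column (`mean` or `anomaly` or
#'   `value`; the first present is used).
#' @param span Smoother window full width, ka (default 2).
#' @return Tibble `(age, trend, residual)`.
#' @export
centennial_residuals <- function(data, span = 2) {
  col <- intersect(c("mean", "anomaly", "value"), names(data))[1]
  if (is.na(col)) abort("`data` needs a value column (mean/anomaly/value).")
  x <- data$age
  y <- data[[col]]
  ok <- is.finite(y)
  if (diff(range(x)) <= span) abort("`span` exceeds the record length.")
  h <- span / 2
  trend <- vapply(x, function(x0) {
    d <- abs(x[ok] - x0)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (sum(use) < 3) return(NA_real_)
    fit <- lm.wfit(cbind(1, x[ok][use] - x0), y[ok][use], w[use])
    fit$coefficients[1]
  }, numeric(1))
  tibble(age = x, trend = trend, residual = y - trend)
}

#' Re-express a series relative to a reference window
#'
#' Subtracts the mean over a window (default the preindustrial 0.25-0.75 ka)
#' so that anomalies are relative to that baseline.
#'
#' @param data Tibble with `age` and a value column.
#' @param window Reference window `(young, old)`, cal ka BP.
#' @return `data` with the value column shifted.
#' @export
rebaseline <- function(data, window = c(0.25, 0.75)) {
  col <- intersect(c("mean", "anomaly", "value"), names(data))[1]
  if (is.na(col)) abort("`data` needs a value column (mean/anomaly/value).")
  inw <- data$age >= window[1] & data$age <= window[2] & is.finite(data[[col]])
  if (!any(inw)) abort("Series does not cover the reference window.")
  shift <- mean(data[[col]][inw])
  for (c2 in intersect(c("mean", "anomaly", "value", "lower95", "upper95", "running_mean5"),
                       names(data))) {
    data[[c2]] <- data[[c2]] - shift
  }
  data
}
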