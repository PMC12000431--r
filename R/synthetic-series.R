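#' Generate an evenly sampled red-noise test series
#'
#' A stationary AR(1) process with unit marginal variance and the stated
#' lag-1 coefficient, optionally with injected sinusoids — the standard
#' fixture for calibrating wavelet red-noise significance.
#'
#' @param n Number of samples.
#' @param dt Time step (years).
#' @param ar1 Lag-1 autocorrelation coefficient, in `[0, 1)`.
#' @param injected Optional tibble/data frame with columns `period` (years)
#'   and `amplitude` (series units) of sinusoids added to the noise.
#' @param seed Integer seed.
#' @return Tibble `(time, value)` with `time = (0:(n-1)) * dt`.
#' @export
generate_rednoise_series <- function(n, dt, ar1 = 0, injected = NULL, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(dt, "dt", lower = 1e-12)
  check_number(ar1, "ar1", lower = 0)
  if (ar1 >= 1) abort("`ar1` must be < 1.")
  with_seed(seed, {
    innov <- rnorm(n, 0, sqrt(1 - ar1^2))
    x <- as.numeric(stats::filter(innov, ar1, method = "recursive",
                                  init = rnorm(1)))
    t <- (seq_len(n) - 1) * dt
    if (!is.null(injected) && nrow(as.data.frame(injected))) {
      injected <- as.data.frame(injected)
      for (i in seq_len(nrow(injected))) {
        phase <- runif(1, 0, 2 * pi)
        x <- x + injected$amplitude[i] *
          sin(2 * pi * t / injected$period[i] + phase)
      }
    }
    tibble(time = t, value = x)
  })
}

#' Spatial dipole test pattern
#'
#' A smooth, unit-norm east-west (or north-south) dipole on an
#' `n_lat x n_lon` grid, used to plant coupled modes in synthetic fields.
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param orientation `"ew"` (sign flips with longitude) or `"ns"`.
#' @return Matrix `[n_lat, n_lon]` with unit Frobenius norm.
#' @export
dipole_pattern <- function(n_lat, n_lon, orientation = c("ew", "ns")) {
  orientation <- match.arg(orientation)
  u <- function(m) sin(pi * (seq_len(m) - 0.5) / m)      # smooth taper
  v <- function(m) sin(2 * pi * (seq_len(m) - 0.5) / m)  # one sign change
  P <- if (orientation == "ew") outer(u(n_lat), v(n_lon)) else outer(v(n_lat), u(n_lon))
  P / sqrt(sum(P^2))
}

#' Generate coupled synthetic SLP and water-balance fields
#'
#' Each planted mode contributes a shared standardized time coefficient: the
#' SLP field receives it directly, the moisture field receives a version
#' correlated at `coupling_r`. Spatially correlated noise (smoothed white
#' noise) is added to both. The fixture exercises EOF truncation and CCA with
#' known joint modes.
#'
#' @param n_lat,n_lon,n_years Grid and record dimensions.
#' @param modes List of planted modes, each a list with elements
#'   `slp_pattern`, `wb_pattern` (matrices `[n_lat, n_lon]`), `coupling_r`
#'   in `[0, 1]`, and optional `amplitude` (field units, default 1).
#' @param noise_scale Standard deviation of the cell-level noise
#'   (field units); 0 for noise-free fields.
#' @param mask Logical land mask; default all land.
#' @param lats,lons Coordinates; defaults span 35-55 N, 105-65 W.
#' @param seed Integer seed.
#' @return List with `grid_field` elements `slp` and `wb`, plus
#'   `mode_series`, the planted shared time coefficients (matrix
#'   `[n_years, n_modes]`).
#' @export
generate_coupled_fields <- function(n_lat = 12, n_lon = 16, n_years = 200,
                                    modes = list(), noise_scale = 1,
                                    mask = NULL,
                                    lats = seq(35, 55, length.out = n_lat),
                                    lons = seq(-105, -65, length.out = n_lon),
                                    seed = NULL) {
  check_number(n_years, "n_years", lower = 2)
  for (m in modes) {
    if (!all(dim(m$slp_pattern) == c(n_lat, n_lon)) ||
        !all(dim(m$wb_pattern) == c(n_lat, n_lon))) {
      abort("Planted mode patterns must match the grid dimensions.")
    }
    check_number(m$coupling_r, "coupling_r", lower = 0, upper = 1)
  }
  with_seed(seed, {
    slp <- array(0, c(n_lat, n_lon, n_years))
    wb <- array(0, c(n_lat, n_lon, n_years))
    zs <- matrix(0, n_years, max(1L, length(modes)))
    for (j in seq_along(modes)) {
      m <- modes[[j]]
      amp <- if (is.null(m$amplitude)) 1 else m$amplitude
      z <- rnorm(n_years)
      w <- m$coupling_r * z + sqrt(1 - m$coupling_r^2) * rnorm(n_years)
      zs[, j] <- z
      for (t in seq_len(n_years)) {
        slp[, , t] <- slp[, , t] + amp * z[t] * m$slp_pattern
        wb[, , t] <- wb[, , t] + amp * w[t] * m$wb_pattern
      }
    }
    if (noise_scale > 0) {
      slp <- slp + smoothed_noise(n_lat, n_lon, n_years, noise_scale)
      wb <- wb + smoothed_noise(n_lat, n_lon, n_years, noise_scale)
    }
    list(
      slp = grid_field(slp, lats, lons, seq_len(n_years), mask,
                       units = "hPa", name = "slp"),
      wb = grid_field(wb, lats, lons, seq_len(n_years), mask,
                      units = "mm/a", name = "water_balance"),
      mode_series = zs
    )
  })
}

# white noise smoothed with a 3x3 spatial box kernel, rescaled to `scale` sd
smoothed_noise <- function(n_lat, n_lon, n_years, scale) {
  out <- array(rnorm(n_lat * n_lon * n_years), c(n_lat, n_lon, n_years))
  for (t in seq_len(n_years)) {
    m <- out[, , t]
    padded <- m[c(1, seq_len(n_lat), n_lat), c(1, seq_len(n_lon), n_lon)]
    sm <- (padded[1:n_lat, 1:n_lon] + padded[1:n_lat, 2:(n_lon + 1)] + padded[1:n_lat, 3:(n_lon + 2)] +
           padded[2:(n_lat + 1), 1:n_lon] + padded[2:(n_lat + 1), 2:(n_lon + 1)] + padded[2:(n_lat + 1), 3:(n_lon + 2)] +
           padded[3:(n_lat + 2), 1:n_lon] + padded[3:(n_lat + 2), 2:(n_lon + 1)] + padded[3:(n_lat + 2), 3:(n_lon + 2)]) / 9
    out[, , t] <- sm
  }
  out * scale / sd(out)
}
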