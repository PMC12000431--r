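#' Mean annual biotemperature (MABT)
#'
#' The annual average of monthly mean temperatures with sub-zero months
#' contributing zero: `sum(pmax(t, 0)) / 12`. MABT is the thermal driver of
#' the potential-evapotranspiration estimate used throughout the package.
#'
#' @param monthly_t Numeric vector of 12 monthly mean temperatures (degrees C),
#'   or a matrix with 12 columns (one row per site/cell).
#' @return A non-negative numeric scalar (or vector, for matrix input) in
#'   degrees C.
#' @seealso [pet_annual()], [water_balance()], [gdd5()]
#' @export
#' @examples
#' mabt(rep(10, 12))
#' mabt(c(rep(15, 6), rep(-5, 6)))
mabt <- function(monthly_t) {
  m <- as_month_matrix(monthly_t)
  rowSums(pmax(m, 0)) / 12
}

#' Annual potential evapotranspiration from biotemperature
#'
#' PET (mm/a) is a fixed linear function of mean annual biotemperature,
#' `PET = 58.93 * MABT`, the convention used to pair pollen calibration data
#' with climate-model output on a common moisture scale.
#'
#' @param mabt Mean annual biotemperature, degrees C (non-negative; vectorized).
#' @return PET in mm/a.
#' @export
#' @examples
#' pet_annual(mabt(rep(10, 12)))
pet_annual <- function(mabt) {
  if (any(!is.finite(mabt))) abort("`mabt` must be finite.")
  if (any(mabt < 0)) abort("`mabt` must be non-negative (biotemperature).")
  58.93 * mabt
}

#' Annual water balance
#'
#' Annual precipitation minus potential evapotranspiration (P - PET), mm/a.
#' Negative values indicate a moisture deficit.
#'
#' @param annual_p Annual total precipitation, mm/a.
#' @param pet Annual potential evapotranspiration, mm/a.
#' @return Water balance in mm/a (vectorized).
#' @export
water_balance <- function(annual_p, pet) {
  if (any(!is.finite(annual_p)) || any(!is.finite(pet))) {
    abort("`annual_p` and `pet` must be finite.")
  }
  annual_p - pet
}

#' Growing degree days above 5 degrees C
#'
#' Daily mean temperatures are interpolated from a single-harmonic sine
#' regression fitted to the 12 monthly means at the month midpoints of a
#' non-leap calendar (year length 365.25 d), and degree days are summed as
#' `sum(pmax(T(d) - 5, 0))` over a daily grid.
#'
#' @inheritParams mabt
#' @return GDD5 in degree C days (scalar or vector).
#' @export
#' @examples
#' gdd5(rep(10, 12)) # flat year: 5 degC x 365 d = 1825
gdd5 <- function(monthly_t) {
  m <- as_month_matrix(monthly_t)
  mid <- month_midpoints()
  ang <- 2 * pi * mid / 365.25
  X <- cbind(1, sin(ang), cos(ang))
  # least-squares sine fit per row, then daily evaluation
  beta <- t(qr.solve(X, t(m)))
  d <- seq_len(365)
  angd <- 2 * pi * d / 365.25
  Xd <- cbind(1, sin(angd), cos(angd))
  daily <- beta %*% t(Xd)
  rowSums(pmax(daily - 5, 0))
}

as_month_matrix <- function(monthly_t) {
  if (is.matrix(monthly_t)) {
    if (ncol(monthly_t) != 12L) abort("`monthly_t` matrix must have 12 columns.")
    m <- monthly_t
  } else {
    if (length(monthly_t) != 12L) abort("`monthly_t` must have exactly 12 values.")
    m <- matrix(monthly_t, nrow = 1L)
  }
  if (any(!is.finite(m))) abort("`monthly_t` must be finite.")
  m
}

month_midpoints <- function() {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(len) - len / 2
}

#' Monthly climatology to water balance, vectorized over grid cells
#'
#' Convenience wrapper chaining [mabt()], [pet_annual()] and [water_balance()]
#' for per-cell monthly stacks.
#'
#' @param monthly_t Matrix of monthly mean temperatures (rows = cells, 12 cols).
#' @param annual_p Vector of annual precipitation totals, mm/a.
#' @return Tibble with columns `mabt`, `pet`, `water_balance`.
#' @export
climatology_water_balance <- function(monthly_t, annual_p) {
  b <- mabt(monthly_t)
  if (length(annual_p) != length(b)) abort("`annual_p` length must match rows of `monthly_t`.")
  if (any(annual_p < 0)) abort("`annual_p` must be non-negative.")
  p <- pet_annual(b)
  tibble(mabt = b, pet = p, water_balance = water_balance(annual_p, p))
}
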