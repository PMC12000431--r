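#' Regional extraction boxes
#'
#' The default boxes coincide with the three pollen site clusters:
#' Midwest (MW) 42-51N / 92-100W, Great Lakes (GL) 40-47N / 85-90W, and
#' Northeast (NE) 40-47N / 69-75W with ocean cells excluded. Longitudes are
#' in [-180, 180].
#'
#' @return Tibble `(region, lat_min, lat_max, lon_min, lon_max, ocean_excluded)`.
#' @export
region_boxes <- function() {
  tibble(
    region = c("MW", "GL", "NE"),
    lat_min = c(42, 40, 40), lat_max = c(51, 47, 47),
    lon_min = c(-100, -90, -75), lon_max = c(-92, -85, -69),
    ocean_excluded = c(FALSE, FALSE, TRUE)
  )
}

#' Area-weighted regional mean of a gridded field
#'
#' Cosine-latitude weighted mean over the cells inside a box, excluding
#' ocean cells when the box says so.
#'
#' @param field A [grid_field()].
#' @param box One-row tibble with `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   and optionally `ocean_excluded` (a row of [region_boxes()]).
#' @return Tibble `(time, value)` of the regional mean series.
#' @export
extract_region <- function(field, box) {
  stopifnot(inherits(field, "grid_field"))
  ilat <- which(field$lats >= box$lat_min & field$lats <= box$lat_max)
  ilon <- which(field$lons >= box$lon_min & field$lons <= box$lon_max)
  if (!length(ilat) || !length(ilon)) abort("Box selects no grid cells.")
  sel_mask <- field$mask[ilat, ilon, drop = FALSE]
  ocean_excluded <- "ocean_excluded" %in% names(box) && isTRUE(box$ocean_excluded)
  if (!ocean_excluded) sel_mask[] <- TRUE
  if (!any(sel_mask)) abort("Box selects no land cells.")
  w <- outer(cos(field$lats[ilat] * pi / 180), rep(1, length(ilon)))
  w[!sel_mask] <- 0
  w <- w / sum(w)
  vals <- vapply(seq_along(field$times), function(t) {
    sum(field$values[ilat, ilon, t] * w)
  }, numeric(1))
  tibble(time = field$times, value = vals)
}

#' Bin an annual series into fixed-width means with error bands
#'
#' Per-bin mean and half-width `2 * sd / sqrt(n)` (n = samples in the bin, 50
#' for full 50-yr bins of annual data; trailing partial bins use their actual
#' count).
#'
#' @param data Tibble `(time, value)`.
#' @param bin_width Bin width in time units (default 50).
#' @return Tibble `(bin_mid, mean, half_width, n)`.
#' @export
bin_series <- function(data, bin_width = 50) {
  if (!nrow(data)) abort("`data` is empty.")
  t0 <- min(data$time)
  data %>%
    mutate(bin = floor((.data$time - t0) / bin_width)) %>%
    group_by(.data$bin) %>%
    summarise(
      bin_mid = t0 + (.data$bin[1] + 0.5) * bin_width,
      mean = mean(.data$value),
      half_width = if (n() > 1) 2 * sd(.data$value) / sqrt(n()) else 0,
      n = n(), .groups = "drop"
    ) %>%
    select(!"bin")
}

#' Correct systematic sea-level-pressure offsets against a reference state
#'
#' Subtracts the scalar difference of the global, area-weighted, time-mean
#' SLP between a paleo state and the reference (preindustrial) state from
#' every cell, removing non-dynamical offsets (lower sea level, ice loading)
#' while leaving every spatial gradient untouched.
#'
#' @param field,reference `grid_field`s on the same grid.
#' @return The corrected `grid_field`.
#' @export
slp_offset_correction <- function(field, reference) {
  stopifnot(inherits(field, "grid_field"), inherits(reference, "grid_field"))
  if (!isTRUE(all.equal(field$lats, reference$lats)) ||
      !isTRUE(all.equal(field$lons, reference$lons))) {
    abort("`field` and `reference` must share the same grid.")
  }
  offset <- global_mean(field) - global_mean(reference)
  field$values <- field$values - offset
  field
}

global_mean <- function(field) {
  w <- outer(cos(field$lats * pi / 180), rep(1, length(field$lons)))
  w <- w / sum(w)
  mean(vapply(seq_along(field$times), function(t) {
    sum(field$values[, , t] * w)
  }, numeric(1)))
}

#' Truncated empirical orthogonal function basis of a field
#'
#' Area-weighted (sqrt-cos-latitude) EOFs of the per-cell time anomalies,
#' retaining the leading modes with their principal-component series and
#' variance fractions. Patterns are orthonormal in the weighted metric.
#'
#' @param field A [grid_field()].
#' @param n_modes Modes retained (default 5).
#' @param land_only Restrict to land-mask cells (default `FALSE`).
#' @return An `eof_basis`: `patterns` (cells x modes), `pcs` (time x modes),
#'   `variance_fraction`, `total_variance`, cell coordinates and weights.
#' @export
eof_truncate <- function(field, n_modes = 5, land_only = FALSE) {
  stopifnot(inherits(field, "grid_field"))
  fs <- field_space_matrix(field, land_only = land_only)
  X <- fs$X
  nt <- nrow(X)
  if (n_modes > min(dim(X))) abort("`n_modes` exceeds the field rank.")
  X <- sweep(X, 2, colMeans(X))
  w <- sqrt(cos(fs$cells$lat * pi / 180))
  Xw <- sweep(X, 2, w, "*")
  sv <- svd(Xw, nu = n_modes, nv = n_modes)
  ev <- sv$d^2 / (nt - 1)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_modes)], n_modes)
  structure(
    list(
      patterns = sv$v,
      pcs = pcs,
      variance_fraction = ev[seq_len(n_modes)] / sum(ev),
      total_variance = sum(ev),
      cells = fs$cells, weights = w,
      times = field$times, n_modes = n_modes,
      name = field$name, units = field$units,
      anomalies = Xw
    ),
    class = "eof_basis"
  )
}

#' @export
print.eof_basis <- function(x, ...) {
  cat(sprintf("EOF basis of `%s`: %d modes over %d cells x %d times; variance fractions %s\n",
              x$name, x$n_modes, nrow(x$cells), length(x$times),
              paste(round(100 * x$variance_fraction, 1), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a field from its EOF basis
#'
#' @param basis An `eof_basis`.
#' @param n_modes Modes used (default all retained).
#' @return Matrix (time x cells) of reconstructed weighted anomalies.
#' @export
eof_reconstruct <- function(basis, n_modes = basis$n_modes) {
  basis$pcs[, seq_len(n_modes), drop = FALSE] %*%
    t(basis$patterns[, seq_len(n_modes), drop = FALSE])
}

#' Canonical correlation analysis of two EOF-truncated fields
#'
#' Finds pairs of linear combinations of the two truncated PC spaces that are
#' maximally correlated, maps the canonical patterns back to grid space by
#' regressing each field's (weighted) anomalies on the normalized canonical
#' time coefficients, and reports per-pattern explained variance relative to
#' each field's total variance. Canonical correlations are returned in their
#' natural descending order and are never re-sorted by explained variance
#' (the leading pair maximizes joint correlation, not individual variance).
#' Significance is assessed by a moving-block permutation of one field's time
#' axis, respecting autocorrelation.
#'
#' @param x_basis,y_basis `eof_basis` objects on a shared time axis (e.g. SLP
#'   and water balance).
#' @param n_perm Permutations for the significance test (default 999).
#' @param block Block length (time steps) for the moving-block permutation
#'   (default 10).
#' @param seed Integer seed for the permutation.
#' @return A `cca_result`: canonical correlations, grid-space patterns and
#'   time coefficients per pair, explained variance per field, p-values.
#' @export
cca <- function(x_basis, y_basis, n_perm = 999, block = 10, seed = NULL) {
  stopifnot(inherits(x_basis, "eof_basis"), inherits(y_basis, "eof_basis"))
  X <- x_basis$pcs
  Y <- y_basis$pcs
  if (nrow(X) != nrow(Y)) abort("The two bases must share a time axis.")
  nt <- nrow(X)
  if (nt <= max(ncol(X), ncol(Y))) abort("Fewer time steps than retained modes.")
  cc <- stats::cancor(X, Y)
  npair <- length(cc$cor)
  U <- scale(X, center = cc$xcenter, scale = FALSE) %*% cc$xcoef[, seq_len(npair), drop = FALSE]
  V <- scale(Y, center = cc$ycenter, scale = FALSE) %*% cc$ycoef[, seq_len(npair), drop = FALSE]
  U <- scale(U)
  V <- scale(V)

  x_patterns <- crossprod(x_basis$anomalies, U) / (nt - 1)  # regression maps
  y_patterns <- crossprod(y_basis$anomalies, V) / (nt - 1)
  # sign convention: X pattern's max-abs cell positive; flip pairs together
  for (m in seq_len(npair)) {
    i <- which.max(abs(x_patterns[, m]))
    if (x_patterns[i, m] < 0) {
      x_patterns[, m] <- -x_patterns[, m]; U[, m] <- -U[, m]
      y_patterns[, m] <- -y_patterns[, m]; V[, m] <- -V[, m]
    }
  }
  x_var <- colSums(x_patterns^2) / x_basis$total_variance
  y_var <- colSums(y_patterns^2) / y_basis$total_variance

  pvals <- rep(NA_real_, npair)
  if (n_perm > 0) {
    perm_cor <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        idx <- block_permute(nt, block)
        stats::cancor(X, Y[idx, , drop = FALSE])$cor[seq_len(npair)]
      }, numeric(npair))
    })
    if (npair == 1L) perm_cor <- matrix(perm_cor, nrow = 1L)
    pvals <- vapply(seq_len(npair), function(m) {
      (1 + sum(perm_cor[m, ] >= cc$cor[m])) / (n_perm + 1)
    }, numeric(1))
  }
  structure(
    list(
      r_canon = cc$cor, p_value = pvals,
      x_patterns = x_patterns, y_patterns = y_patterns,
      x_coefficients = U, y_coefficients = V,
      x_variance = x_var, y_variance = y_var,
      x_cells = x_basis$cells, y_cells = y_basis$cells,
      times = x_basis$times,
      x_name = x_basis$name, y_name = y_basis$name
    ),
    class = "cca_result"
  )
}

# circular moving-block permutation of 1..n
block_permute <- function(n, block) {
  block <- max(1L, min(as.integer(block), n))
  nblocks <- ceiling(n / block)
  starts <- sample.int(n, nblocks, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) ((s - 1 + 0:(block - 1)) %% n) + 1))
  idx[seq_len(n)]
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA %s ~ %s: %d canonical pairs\n", x$x_name, x$y_name, length(x$r_canon)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.cca_result <- function(x, ...) {
  tibble(
    pair = seq_along(x$r_canon),
    r_canon = x$r_canon,
    p_value = x$p_value,
    x_variance = x$x_variance,
    y_variance = x$y_variance
  )
}

#' @export
glance.cca_result <- function(x, ...) {
  tibble(n_pairs = length(x$r_canon), r1 = x$r_canon[1],
         p1 = x$p_value[1], n_times = length(x$times))
}

#' Congruence between two spatial patterns
#'
#' Absolute uncentered correlation `|sum(a*b)| / sqrt(sum(a^2) sum(b^2))`,
#' the usual measure of pattern recovery (1 = identical up to sign/scale).
#'
#' @param a,b Numeric patterns (vectors or matrices of equal size).
#' @return A value in `[0, 1]`.
#' @export
pattern_congruence <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) abort("Patterns must have equal size.")
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
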