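make_uniform_field <- function(value = 1, n_lat = 4, n_lon = 5, n_t = 3,
                               lats = seq(40, 46, length.out = n_lat),
                               lons = seq(-100, -92, length.out = n_lon)) {
  grid_field(array(value, c(n_lat, n_lon, n_t)), lats, lons, seq_len(n_t))
}

test_that("regional extraction is the cosine-latitude weighted mean", {
  f <- make_uniform_field(3)
  box <- tibble::tibble(lat_min = 40, lat_max = 46, lon_min = -100, lon_max = -92)
  expect_equal(extract_region(f, box)$value, rep(3, 3))
  # one-cell box returns that cell's series
  v <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  f2 <- grid_field(v, seq(40, 46, length.out = 4), seq(-100, -92, length.out = 5), 1:3)
  box1 <- tibble::tibble(lat_min = 39.9, lat_max = 40.1, lon_min = -100.1, lon_max = -99.9)
  expect_equal(extract_region(f2, box1)$value, v[1, 1, ])
  # two cells at different latitudes: hand-computed cosine weighting
  v3 <- array(0, c(2, 1, 1)); v3[1, 1, 1] <- 1; v3[2, 1, 1] <- 2
  f3 <- grid_field(v3, c(40, 60), -95, 1)
  box3 <- tibble::tibble(lat_min = 35, lat_max = 65, lon_min = -96, lon_max = -94)
  w <- cos(c(40, 60) * pi / 180)
  expect_equal(extract_region(f3, box3)$value, sum(c(1, 2) * w) / sum(w))
  expect_error(extract_region(f, tibble::tibble(lat_min = 80, lat_max = 85,
                                                lon_min = 0, lon_max = 5)),
               "no grid cells")
})

test_that("the ocean flag drops masked cells from the regional mean", {
  v <- array(1, c(2, 2, 1)); v[1, 1, 1] <- 100
  mask <- matrix(TRUE, 2, 2); mask[1, 1] <- FALSE
  f <- grid_field(v, c(41, 42), c(-71, -70), 1, mask)
  box <- tibble::tibble(lat_min = 40, lat_max = 47, lon_min = -75, lon_max = -69,
                        ocean_excluded = TRUE)
  expect_equal(extract_region(f, box)$value, 1)
  box$ocean_excluded <- FALSE
  expect_gt(extract_region(f, box)$value, 1)
})

test_that("series binning reports the two-sigma standard error band", {
  const <- tibble::tibble(time = 0:99, value = 7)
  b <- bin_series(const, 50)
  expect_equal(nrow(b), 2L)
  expect_equal(b$mean, c(7, 7))
  expect_equal(b$half_width, c(0, 0))
  expect_equal(b$n, c(50L, 50L))
  set.seed(1)
  g <- tibble::tibble(time = 0:4999, value = rnorm(5000))
  bg <- bin_series(g, 50)
  expect_equal(mean(bg$half_width), 2 / sqrt(50), tolerance = 0.05)
})

test_that("pressure offset correction removes the scalar bias only", {
  set.seed(2)
  ref <- make_uniform_field(0)
  ref$values <- array(rnorm(60), c(4, 5, 3))
  shifted <- ref
  shifted$values <- ref$values + 5
  corr <- slp_offset_correction(shifted, ref)
  expect_equal(corr$values, ref$values, tolerance = 1e-12)
  # gradients preserved for an arbitrary field
  f <- ref; f$values <- ref$values * 2 + 7
  cf <- slp_offset_correction(f, ref)
  expect_equal(cf$values[1, 1, ] - cf$values[3, 4, ],
               f$values[1, 1, ] - f$values[3, 4, ])
  gm <- function(x) {
    w <- outer(cos(x$lats * pi / 180), rep(1, length(x$lons))); w <- w / sum(w)
    mean(vapply(seq_along(x$times), function(t) sum(x$values[, , t] * w), numeric(1)))
  }
  expect_equal(gm(cf), gm(ref), tolerance = 1e-9)
  other <- make_uniform_field(0, lats = seq(10, 20, length.out = 4))
  expect_error(slp_offset_correction(f, other), "same grid")
})

test_that("EOF truncation recovers rank structure and planted variance ratios", {
  set.seed(3)
  nlat <- 6; nlon <- 8; nt <- 120
  p1 <- dipole_pattern(nlat, nlon, "ew")
  rank1 <- array(0, c(nlat, nlon, nt))
  u <- rnorm(nt)
  for (t in seq_len(nt)) rank1[, , t] <- u[t] * p1
  f1 <- grid_field(rank1, seq(40, 50, length.out = nlat),
                   seq(-100, -85, length.out = nlon), seq_len(nt))
  e1 <- eof_truncate(f1, 2)
  expect_equal(e1$variance_fraction[1], 1, tolerance = 1e-9)
  # two orthogonal planted modes with exactly 2:1 variance: orthonormalize
  # the planted scores so sample variances match the construction
  p2 <- dipole_pattern(nlat, nlon, "ns")
  two <- array(0, c(nlat, nlon, nt))
  u1 <- as.numeric(scale(u))
  u2 <- rnorm(nt)
  u2 <- as.numeric(scale(residuals(lm(u2 ~ u1))))
  for (t in seq_len(nt)) two[, , t] <- sqrt(2) * u1[t] * p1 + u2[t] * p2
  f2 <- grid_field(two, rep(45, nlat) + seq(0, 1, length.out = nlat),
                   seq(-100, -85, length.out = nlon), seq_len(nt))
  e2 <- eof_truncate(f2, 3)
  expect_equal(e2$variance_fraction[1] / e2$variance_fraction[2], 2,
               tolerance = 0.05)
  # patterns orthonormal; full basis reconstructs the field exactly
  G <- crossprod(e2$patterns)
  expect_equal(G, diag(ncol(e2$patterns)), tolerance = 1e-8, ignore_attr = TRUE)
  efull <- eof_truncate(f2, min(nt, nlat * nlon))
  expect_equal(eof_reconstruct(efull), efull$anomalies, tolerance = 1e-8)
  expect_error(eof_truncate(f2, 1000), "rank")
})

test_that("EOF results are invariant to grid-cell relabeling", {
  set.seed(4)
  f <- generate_coupled_fields(6, 8, 60, noise_scale = 1, seed = 5)$slp
  flipped <- grid_field(f$values[6:1, , ], rev(f$lats), f$lons, f$times,
                        f$mask[6:1, ])
  e1 <- eof_truncate(f, 3)
  e2 <- eof_truncate(flipped, 3)
  expect_equal(e1$variance_fraction, e2$variance_fraction, tolerance = 1e-8)
})

test_that("identical bases give perfect canonical correlations", {
  f <- generate_coupled_fields(6, 8, 80, noise_scale = 1, seed = 6)$slp
  e <- eof_truncate(f, 3)
  cc <- cca(e, e, n_perm = 0)
  expect_equal(cc$r_canon, rep(1, 3), tolerance = 1e-8)
})

test_that("canonical correlations are ordered with orthogonal time coefficients", {
  fl <- generate_coupled_fields(6, 8, 100, noise_scale = 1, seed = 7)
  cc <- cca(eof_truncate(fl$slp, 4), eof_truncate(fl$wb, 4), n_perm = 0)
  expect_true(all(diff(cc$r_canon) <= 1e-12))
  expect_true(all(cc$r_canon >= 0 & cc$r_canon <= 1))
  for (M in list(cc$x_coefficients, cc$y_coefficients)) {
    cmat <- cor(M)
    expect_lt(max(abs(cmat[upper.tri(cmat)])), 1e-8)
  }
  # the leading pair maximizes correlation over random probes in PC space
  ex <- eof_truncate(fl$slp, 4); ey <- eof_truncate(fl$wb, 4)
  set.seed(8)
  probes <- replicate(200, {
    a <- rnorm(4); b <- rnorm(4)
    abs(cor(ex$pcs %*% a, ey$pcs %*% b))
  })
  expect_lte(max(probes), cc$r_canon[1] + 1e-10)
})

test_that("independent noise fields rarely reach permutation significance", {
  hits <- vapply(1:12, function(s) {
    fx <- generate_coupled_fields(5, 6, 80, noise_scale = 1, seed = 900 + s)$slp
    fy <- generate_coupled_fields(5, 6, 80, noise_scale = 1, seed = 950 + s)$wb
    cc <- cca(eof_truncate(fx, 3), eof_truncate(fy, 3), n_perm = 99, seed = s)
    cc$p_value[1] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})

test_that("pattern congruence is scale- and sign-invariant", {
  p <- dipole_pattern(5, 7)
  expect_equal(pattern_congruence(p, -3 * p), 1)
  expect_lt(pattern_congruence(p, dipole_pattern(5, 7, "ns")), 0.2)
  expect_error(pattern_congruence(1:3, 1:4), "equal size")
})
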