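test_that("a noisy monotone ramp is rising at millennial bandwidths", {
  set.seed(1)
  t <- seq(0, 10000, 50)
  ramp <- tibble::tibble(time = t, value = 0.01 * t + rnorm(length(t), 0, 5))
  sz <- sizer_map(ramp, bandwidths = 10^seq(log10(100), log10(4000), length.out = 16))
  wide <- dplyr::filter(tidy(sz), bandwidth >= 500)
  expect_true(all(wide$class == "rising"))
})

test_that("a constant series is flat everywhere", {
  s <- tibble::tibble(time = seq_len(50), value = 2)
  sz <- sizer_map(s, bandwidths = c(5, 20))
  cls <- tidy(sz)$class
  expect_true(all(cls %in% c("flat", "insufficient")))
  expect_true(any(cls == "flat"))
})

test_that("sign-flipping the input swaps rising and falling cells exactly", {
  set.seed(3)
  t <- seq(0, 5000, 50)
  s <- tibble::tibble(time = t, value = sin(t / 800) * 10 + rnorm(length(t)))
  a <- tidy(sizer_map(s, bandwidths = c(300, 1000)))
  b <- tidy(sizer_map(dplyr::mutate(s, value = -value), bandwidths = c(300, 1000)))
  swap <- c(rising = "falling", falling = "rising", flat = "flat",
            insufficient = "insufficient")
  expect_identical(unname(swap[a$class]), b$class)
})

test_that("sparse kernel windows are marked insufficient", {
  s <- tibble::tibble(time = seq(0, 1100, 100), value = rnorm(12))
  sz <- sizer_map(s, bandwidths = c(30, 1000))
  narrow <- dplyr::filter(tidy(sz), bandwidth == 30)
  expect_true(all(narrow$class == "insufficient"))
  expect_error(sizer_map(s[1:9, ]), "10 points")
  expect_error(sizer_map(tibble::tibble(time = c(1, 3, 2, 4:10), value = rnorm(10))),
               "increasing")
})

test_that("identical columns load entirely on the first component", {
  grid <- seq(0.25, 11, 0.05)
  base <- sin(grid)
  s <- purrr::map_dfr(1:5, ~tibble::tibble(site_id = paste0("s", .x),
                                           age = grid, anomaly = base))
  p <- pca_reconstructions(s)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("planted orthogonal modes are recovered with their variance ratio", {
  grid <- seq(0.25, 11, 0.05)
  nt <- length(grid)
  set.seed(4)
  u1 <- sqrt(2) * sin(2 * pi * seq_len(nt) / nt)   # shared trend score
  u2 <- sqrt(2) * cos(2 * pi * seq_len(nt) / nt)   # orthogonal mode score
  n_sites <- 16
  lon <- seq(-100, -70, length.out = n_sites)
  p1 <- rep(1, n_sites) / sqrt(n_sites)
  p2 <- rep(c(1, -1), each = n_sites / 2) / sqrt(n_sites)
  amp1 <- sqrt(2); amp2 <- 1                        # variance ratio 2:1
  M <- outer(amp1 * u1, p1) + outer(amp2 * u2, p2) +
    matrix(rnorm(nt * n_sites, 0, 0.01), nt)
  s <- purrr::map_dfr(seq_len(n_sites), function(i) {
    tibble::tibble(site_id = sprintf("s%02d", i), age = grid, anomaly = M[, i])
  })
  p <- pca_reconstructions(s, site_lon = setNames(lon, sprintf("s%02d", seq_len(n_sites))))
  expect_equal(p$variance_fraction[1] / p$variance_fraction[2], 2, tolerance = 0.1)
  # shared mode: all loadings one sign; contrast mode: split by longitude
  l <- p$loadings
  expect_true(all(l$PC1 > 0))
  east <- l$PC2[lon > -85]; west <- l$PC2[lon < -85]
  expect_true(all(sign(east) == sign(east[1])))
  expect_true(all(sign(west) == -sign(east[1])))
  # orientation: eastmost-minus-westmost PC2 contrast is negative
  expect_lt(l$PC2[which.max(lon)] - l$PC2[which.min(lon)], 0)
})

test_that("eigenvalues conserve total variance and scores are orthogonal", {
  grid <- seq(0.25, 11, 0.05)
  set.seed(5)
  s <- purrr::map_dfr(1:6, ~tibble::tibble(site_id = paste0("s", .x), age = grid,
                                           anomaly = rnorm(length(grid))))
  p <- pca_reconstructions(s)
  wide <- tidyr::pivot_wider(s, id_cols = "age", names_from = "site_id",
                             values_from = "anomaly")
  M <- scale(as.matrix(wide[, -1]), scale = FALSE)
  expect_equal(sum(p$eigenvalues), sum(M^2) / (nrow(M) - 1), tolerance = 1e-8)
  sc <- as.matrix(p$scores[, -1])
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_lte(sum(p$variance_fraction), 1 + 1e-9)
})

test_that("sites not covering the window are excluded before decomposition", {
  grid <- seq(0.25, 11, 0.05)
  full <- purrr::map_dfr(1:3, ~tibble::tibble(site_id = paste0("s", .x),
                                              age = grid, anomaly = rnorm(length(grid))))
  short <- tibble::tibble(site_id = "short", age = grid[grid < 6],
                          anomaly = rnorm(sum(grid < 6)))
  p <- pca_reconstructions(dplyr::bind_rows(full, short))
  expect_setequal(p$loadings$site_id, c("s1", "s2", "s3"))
})
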