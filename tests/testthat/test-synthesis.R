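test_that("site filtering applies each criterion with its printed threshold", {
  sites <- dplyr::bind_rows(
    make_site_row("ok", 30, 5, 10.0, 500),
    make_site_row("few_samples", 29, 5, 10.5, 500),
    make_site_row("few_dates", 40, 4, 10.5, 500),
    make_site_row("young", 40, 5, 9.9, 500),
    make_site_row("dry_margin", 40, 5, 10.5, -250),
    make_site_row("wet_margin", 40, 5, 10.5, 1200),
    make_site_row("no_meta", NA, 5, 10.5, 500)
  )
  out <- filter_sites(sites)
  expect_equal(out$accepted,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reason[-1],
               c("too_few_samples", "too_few_dates", "bottom_too_young",
                 "wb_outside_margin", "wb_outside_margin", "missing_metadata"))
  # -250 fails because the margin bound is -348 + 150 = -198
  expect_true(filter_sites(dplyr::mutate(sites[1, ], modern_wb = -197))$accepted)
  expect_false(filter_sites(dplyr::mutate(sites[1, ], modern_wb = -199))$accepted)
})

test_that("the high-resolution filter applies the stricter pair", {
  hi <- make_site_row("hires", 125, 9, 11, 500)
  lo <- make_site_row("lores", 124, 9, 11, 500)
  expect_true(filter_sites(hi, highres = TRUE)$accepted)
  expect_false(filter_sites(lo, highres = TRUE)$accepted)
  expect_false(filter_sites(make_site_row("fewd", 130, 8, 11, 500),
                            highres = TRUE)$accepted)
  expect_true(filter_sites(lo)$accepted)  # passes the ordinary filter
})

test_that("alignment and interpolation reproduce linear records exactly", {
  const <- tibble::tibble(age = c(0.1, 1.3, 2.2, 5.7, 9.1), value = 7)
  a <- align_and_interpolate(const)
  expect_true(all(a$anomaly == 0))
  expect_true(all(abs(a$age / 0.05 - round(a$age / 0.05)) < 1e-9))
  # a linear ramp sampled irregularly interpolates without error
  ramp <- tibble::tibble(age = c(0, 0.31, 1.7, 3.33, 6.2, 10), value = NA)
  ramp$value <- 10 * ramp$age
  ar <- align_and_interpolate(ramp)
  expect_equal(ar$anomaly, 10 * ar$age - mean(10 * ar$age[ar$age <= 4]))
  # a series already on the grid is returned unchanged (up to the baseline)
  ongrid <- tibble::tibble(age = seq(0, 10, 0.05), value = sin(seq(0, 10, 0.05)))
  ag <- align_and_interpolate(ongrid)
  expect_equal(ag$anomaly + mean(ongrid$value[ongrid$age <= 4]), ongrid$value)
  expect_error(align_and_interpolate(tibble::tibble(age = c(6, 7, 8), value = 1:3)),
               "no_baseline_overlap")
})

test_that("a single site synthesizes to itself with collapsed bands", {
  s <- tibble::tibble(site_id = "a", age = seq(0, 5, 0.05),
                      anomaly = sin(seq(0, 5, 0.05)))
  syn <- regional_synthesis(s, n_boot = 50, seed = 1)
  expect_equal(syn$mean, s$anomaly)
  expect_equal(syn$lower95, syn$mean)
  expect_equal(syn$upper95, syn$mean)
  expect_true(all(syn$n_sites == 1))
})

test_that("identical sites give zero-width bands and constants give zeros", {
  grid <- seq(0, 6, 0.05)
  s <- purrr::map_dfr(1:4, ~tibble::tibble(site_id = paste0("s", .x),
                                           age = grid, anomaly = cos(grid)))
  syn <- regional_synthesis(s, n_boot = 100, seed = 2)
  expect_equal(syn$upper95 - syn$lower95, rep(0, length(grid)))
  zero <- dplyr::mutate(s, anomaly = 0)
  expect_true(all(regional_synthesis(zero, n_boot = 50, seed = 3)$mean == 0))
})

test_that("bootstrap bands cover an iid-noise truth near the nominal rate", {
  grid <- seq(0, 8, 0.05)
  truth <- 30 * sin(grid)
  cov <- vapply(1:10, function(s) {
    set.seed(s)
    sites <- purrr::map_dfr(1:20, function(i) {
      tibble::tibble(site_id = sprintf("s%02d", i), age = grid,
                     anomaly = truth + rnorm(length(grid), 0, 15))
    })
    syn <- regional_synthesis(sites, n_boot = 400, seed = s)
    mean(truth >= syn$lower95 & truth <= syn$upper95)
  }, numeric(1))
  expect_equal(mean(cov), 0.95, tolerance = 0.05)
})

test_that("bands widen with between-site variance", {
  grid <- seq(0, 8, 0.05)
  width_at <- function(sd) {
    set.seed(42)
    sites <- purrr::map_dfr(1:12, function(i) {
      tibble::tibble(site_id = sprintf("s%02d", i), age = grid,
                     anomaly = rnorm(length(grid), 0, sd))
    })
    syn <- regional_synthesis(sites, n_boot = 200, seed = 1)
    median(syn$upper95 - syn$lower95)
  }
  expect_lt(width_at(5), width_at(25))
})

test_that("the running mean honors shrinking edges and preserves structure", {
  expect_equal(running_mean(rep(3, 10)), rep(3, 10))
  imp <- running_mean(c(0, 0, 1, 0, 0))
  expect_equal(imp[3], 0.2)
  expect_equal(imp, c(1 / 3, 1 / 4, 1 / 5, 1 / 4, 1 / 3))
  lin <- running_mean(1:11)
  expect_equal(lin[3:9], 3:9)
  expect_error(running_mean(1:5, 4), "odd")
})

test_that("the fixed-span smoother separates trend from centennial signal", {
  age <- seq(0, 10, 0.05)
  trend <- tibble::tibble(age = age, value = 100 * (age / 10)^2)
  r1 <- centennial_residuals(trend)
  expect_lt(max(abs(r1$residual)), 5)  # < 5% of the 100-unit amplitude
  cyc <- tibble::tibble(age = age, value = sin(2 * pi * age / 0.2))
  r2 <- centennial_residuals(cyc)
  expect_gte(var(r2$residual) / var(cyc$value), 0.9)
  const <- tibble::tibble(age = age, value = 4)
  expect_equal(centennial_residuals(const)$residual, rep(0, length(age)))
  expect_error(centennial_residuals(trend[1:10, ]), "record")
})

test_that("rebaselining is idempotent and zeroes constants", {
  age <- seq(0, 2, 0.05)
  s <- tibble::tibble(age = age, value = 5 + age)
  r1 <- rebaseline(s)
  r2 <- rebaseline(r1)
  expect_equal(r1$value, r2$value)
  expect_equal(mean(r1$value[age >= 0.25 & age <= 0.75]), 0)
  expect_true(all(rebaseline(tibble::tibble(age = age, value = 3))$value == 0))
  expect_error(rebaseline(tibble::tibble(age = 5:8, value = 1:4)), "window")
})
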