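test_that("the high-pass filter removes slow and keeps fast oscillations", {
  t <- seq(0, 7950, 50)
  const <- tibble::tibble(time = t, value = 5)
  expect_lt(max(abs(preprocess_series(const, 1000)$value)), 1e-8)
  fast <- tibble::tibble(time = t, value = sin(2 * pi * t / 200))
  expect_gte(sd(preprocess_series(fast, 1000)$value) / sd(fast$value), 0.95)
  slow <- tibble::tibble(time = t, value = sin(2 * pi * t / 5000))
  expect_lte(sd(preprocess_series(slow, 1000)$value) / sd(slow$value), 0.1)
  expect_error(preprocess_series(fast, 80), "Nyquist")
})

test_that("the running-mean option degrades annual series to coarse resolution", {
  t <- 0:999
  s <- tibble::tibble(time = t, value = sin(2 * pi * t / 20) + sin(2 * pi * t / 400))
  f <- preprocess_series(s, highpass_cutoff = 1000, smooth_window = 50)
  # the 20-yr oscillation is averaged out, the 400-yr one survives
  spec <- stats::spec.pgram(stats::ts(f$value, deltat = 1), plot = FALSE)
  p20 <- spec$spec[which.min(abs(spec$freq - 1 / 20))]
  p400 <- spec$spec[which.min(abs(spec$freq - 1 / 400))]
  expect_gt(p400 / p20, 10)
})

test_that("wavelet power scales quadratically while the mask is scale-free", {
  x <- generate_rednoise_series(128, 50, ar1 = 0.4, seed = 1)
  w1 <- morlet_wavelet(x)
  w2 <- morlet_wavelet(dplyr::mutate(x, value = 2 * value))
  expect_equal(w2$power, 4 * w1$power, tolerance = 1e-10)
  expect_identical(w1$mask, w2$mask)
})

test_that("total wavelet power tracks series variance across an ensemble", {
  # scale-weighted total power (the Morlet inversion formula) against the
  # series variance; the reconstruction constant cancels in the correlation
  stats <- vapply(1:20, function(s) {
    x <- generate_rednoise_series(128, 50, ar1 = 0.3, seed = 100 + s)
    set.seed(s)
    x$value <- x$value * runif(1, 0.5, 3)
    wr <- morlet_wavelet(x)
    ff <- 4 * pi / (6 + sqrt(38))
    scales <- wr$period / ff
    total <- sum(sweep(wr$power, 1, scales, "/")) * 0.05 * wr$dt /
      (0.776 * length(wr$time))
    c(total, wr$variance)
  }, numeric(2))
  expect_gte(cor(stats[1, ], stats[2, ]), 0.99)
  # and the inversion-formula estimate is close to the variance itself
  expect_equal(median(stats[1, ] / stats[2, ]), 1, tolerance = 0.25)
})

test_that("a planted cycle produces a contiguous significant band at its period", {
  x <- generate_rednoise_series(160, 50, ar1 = 0.5,
                                injected = data.frame(period = 200, amplitude = 3),
                                seed = 2)
  wr <- morlet_wavelet(x)
  j200 <- which.min(abs(wr$period - 200))
  expect_gt(sum(wr$mask[j200, ]), 0.3 * sum(wr$in_cone[j200, ]))
  periods <- extract_significant_periods(wr)
  expect_true(any(abs(periods$period - 200) / 200 <= 0.1))
})

test_that("two planted cycles are both recovered within ten percent", {
  x <- generate_rednoise_series(256, 50, ar1 = 0.3,
                                injected = data.frame(period = c(200, 450),
                                                      amplitude = c(3, 3)),
                                seed = 3)
  wr <- morlet_wavelet(x)
  p <- extract_significant_periods(wr)
  expect_true(any(abs(p$period - 200) / 200 <= 0.1))
  expect_true(any(abs(p$period - 450) / 450 <= 0.1))
})

test_that("null series yield few or no extracted periodicities", {
  counts <- vapply(1:10, function(s) {
    wr <- morlet_wavelet(generate_rednoise_series(160, 50, ar1 = 0.5, seed = 400 + s))
    nrow(extract_significant_periods(wr))
  }, numeric(1))
  expect_lte(mean(counts), 1)
})

test_that("degenerate wavelet inputs are rejected", {
  expect_error(morlet_wavelet(tibble::tibble(time = 1:10, value = rnorm(10))),
               "32")
  bad <- tibble::tibble(time = seq_len(64), value = c(NA, rnorm(63)))
  expect_error(morlet_wavelet(bad), "missing")
  uneven <- tibble::tibble(time = cumsum(runif(64, 0.5, 2)), value = rnorm(64))
  expect_error(morlet_wavelet(uneven), "uniform")
})

test_that("period densities are normalized and peak at the planted clusters", {
  single <- periodicity_kde(c(200))
  expect_equal(single$period[which.max(single$density)], 200, tolerance = 0.05)
  area <- sum(single$density[-1] * diff(single$period))
  expect_equal(area, 1, tolerance = 1e-2)
  # duplicating the inputs leaves the density unchanged
  d1 <- periodicity_kde(c(180, 200, 220, 430, 450, 470))
  d2 <- periodicity_kde(rep(c(180, 200, 220, 430, 450, 470), 2))
  expect_equal(d1$density, d2$density, tolerance = 1e-12)
  # a bimodal cluster pair yields modes near both planted periods
  dens <- periodicity_kde(c(190, 200, 210, 440, 450, 460),
                          grid = seq(0, 600, 1))
  peaks <- dens$period[which(diff(sign(diff(dens$density))) == -2) + 1]
  expect_true(any(abs(peaks - 200) / 200 <= 0.1))
  expect_true(any(abs(peaks - 450) / 450 <= 0.1))
  expect_error(periodicity_kde(numeric(0)), "empty")
})
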