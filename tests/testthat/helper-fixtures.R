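# Shared synthetic fixtures, built once per test run.

# moderate calibration set used across transfer-function tests
fixture_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_calibration_dataset(400, seed = 42)
    }
    cache
  }
})

# random points on the simplex
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  sweep(m, 1, rowSums(m), "/")
}

# independent brute-force squared-chord oracle (per-taxon loop)
chord_loop <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (sqrt(p[i]) - sqrt(q[i]))^2
  s
}

# minimal nested fossil-site row without generators (metadata control)
make_site_row <- function(site_id = "s1", n_samples = 40, n_dates = 6,
                          bottom_age = 10.5, modern_wb = 500,
                          lat = 45, lon = -90) {
  tibble::tibble(site_id = site_id, lat = lat, lon = lon,
                 modern_wb = modern_wb, n_samples = n_samples,
                 n_dates = n_dates, bottom_age = bottom_age,
                 data = list(tibble::tibble(age = numeric(0))))
}
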