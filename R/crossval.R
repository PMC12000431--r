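#' h-block cross-validation of a transfer function
#'
#' Leave-one-out validation hardened against spatial autocorrelation: for each
#' calibration site, the model is refitted excluding every site within
#' great-circle distance `h_km` of the test site (including the site itself),
#' and the held-out site is predicted. `h_km = 0` reduces to ordinary
#' leave-one-out.
#'
#' @inheritParams mat_fit
#' @param method `"MAT"` or `"BRT"`.
#' @param h_km Exclusion radius in kilometres.
#' @param k MAT analog count.
#' @param brt_args Named list of arguments passed to [brt_fit()] for each fold
#'   (e.g. a smaller `max_trees`). Unless given, the fold models reuse the
#'   tree count selected once on the full dataset, keeping the refits cheap.
#' @param seed Seed for the BRT folds.
#' @return An `hblock_cv` object: per-site held-out predictions plus the
#'   overall coefficient of determination (`glance()` for the summary).
#' @export
hblock_crossvalidate <- function(train, method = c("MAT", "BRT"), target,
                                 h_km = 100, k = 5, brt_args = list(),
                                 seed = NULL) {
  method <- match.arg(method)
  train <- as_calibration(train, attr(train, "taxa"))
  if (!all(c("lat", "lon") %in% names(train))) abort("`train` must have `lat` and `lon` columns.")
  check_number(h_km, "h_km", lower = 0)
  n <- nrow(train)
  taxa <- calibration_taxa(train)
  y <- train[[target]]
  ll <- cbind(train$lon, train$lat)
  Dkm <- geosphere::distm(ll, fun = geosphere::distHaversine) / 1000
  site_id <- if ("site_id" %in% names(train)) as.character(train$site_id) else as.character(seq_len(n))

  fixed_trees <- NULL
  if (method == "BRT" && is.null(brt_args$n_trees)) {
    # select the ensemble size once on the full data, reuse per fold
    full <- do.call(brt_fit, c(list(train = train, target = target, seed = seed), brt_args))
    fixed_trees <- full$n_trees
  }

  pred <- vapply(seq_len(n), function(i) {
    keep <- which(Dkm[i, ] > h_km)
    if (!length(keep)) {
      abort(sprintf("h = %g km empties the training fold for site `%s`.", h_km, site_id[i]))
    }
    fold <- train[keep, ]
    attr(fold, "taxa") <- taxa
    newx <- train[i, ]
    if (method == "MAT") {
      m <- suppressWarnings(mat_fit(fold, target, k = k))
      mat_predict(m, newx)$value
    } else {
      args <- brt_args
      if (!is.null(fixed_trees)) args$n_trees <- fixed_trees
      m <- do.call(brt_fit, c(list(train = fold, target = target, seed = seed), args))
      brt_predict(m, newx)
    }
  }, numeric(1))

  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(
    list(
      method = method, target = target, h_km = h_km,
      predictions = tibble(site_id = site_id, observed = y, predicted = pred),
      r2 = r2
    ),
    class = "hblock_cv"
  )
}

#' @export
print.hblock_cv <- function(x, ...) {
  cat(sprintf("h-block cross-validation (%s, target %s, h = %g km): R2 = %.3f over %d sites\n",
              x$method, x$target, x$h_km, x$r2, nrow(x$predictions)))
  invisible(x)
}

#' @export
tidy.hblock_cv <- function(x, ...) x$predictions

#' @export
glance.hblock_cv <- function(x, ...) {
  tibble(method = x$method, target = x$target, h_km = x$h_km,
         r2 = x$r2, n_sites = nrow(x$predictions))
}
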