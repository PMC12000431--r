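#' Fit a modern-analog (MAT) transfer function
#'
#' MAT reconstructs climate for a fossil assemblage as the inverse
#' squared-chord-distance weighted mean of the `k` compositionally closest
#' modern calibration samples (default five best analogs). A zero-distance
#' analog takes full weight.
#'
#' @param train Calibration tibble (see [as_calibration()]): taxon proportion
#'   columns plus the target climate column.
#' @param target Name of the climate column to calibrate against
#'   (`"tjul"`, `"water_balance"` or `"gdd5"`).
#' @param k Number of analogs (clamped to the training-pool size with a
#'   warning).
#' @return A `mat_model` object.
#' @export
mat_fit <- function(train, target, k = 5) {
  train <- as_calibration(train, attr(train, "taxa"))
  if (!target %in% names(train)) abort(sprintf("Target column `%s` missing from training data.", target))
  if (!nrow(train)) abort("`train` must be nonempty.")
  check_number(k, "k", lower = 1)
  if (k > nrow(train)) {
    warn(sprintf("k = %d exceeds the training pool (%d sites); clamped.", k, nrow(train)))
    k <- nrow(train)
  }
  taxa <- calibration_taxa(train)
  y <- train[[target]]
  if (any(!is.finite(y))) abort("Target column contains non-finite values.")
  structure(
    list(
      method = "MAT",
      target = target,
      k = as.integer(k),
      taxa = taxa,
      composition = composition_matrix(train, taxa),
      y = y,
      site_id = if ("site_id" %in% names(train)) as.character(train$site_id) else as.character(seq_len(nrow(train)))
    ),
    class = c("mat_model", "transfer_model")
  )
}

#' Predict climate from assemblages with a fitted MAT model
#'
#' @param model A `mat_model` from [mat_fit()].
#' @param assemblages Tibble (or matrix) of compositions over the model's
#'   taxonomy; extra columns are ignored.
#' @return Tibble with one row per assemblage: `value` (distance-weighted mean
#'   of the k best analogs' climate) and `min_distance` (squared-chord distance
#'   to the single best analog).
#' @export
mat_predict <- function(model, assemblages) {
  stopifnot(inherits(model, "mat_model"))
  comp <- align_assemblages(assemblages, model$taxa)
  if (!nrow(comp)) abort("`assemblages` is empty.")
  D <- chord_distance_matrix(comp, model$composition)
  k <- model$k
  res <- vapply(seq_len(nrow(comp)), function(i) {
    d <- D[i, ]
    # stable ascending order: ties at the k-th distance broken by site order
    idx <- order(d)[seq_len(k)]
    dk <- d[idx]
    yk <- model$y[idx]
    exact <- dk < 1e-12
    val <- if (any(exact)) mean(yk[exact]) else sum(yk / dk) / sum(1 / dk)
    c(val, dk[1])
  }, numeric(2))
  tibble(value = res[1, ], min_distance = res[2, ])
}

#' @export
predict.mat_model <- function(object, newdata, ...) mat_predict(object, newdata)

#' @export
print.mat_model <- function(x, ...) {
  cat(sprintf("MAT transfer function for `%s`: %d training samples, k = %d analogs\n",
              x$target, length(x$y), x$k))
  invisible(x)
}

#' @export
glance.mat_model <- function(x, ...) {
  tibble(method = "MAT", target = x$target, n_train = length(x$y), k = x$k)
}

align_assemblages <- function(assemblages, taxa) {
  if (is.matrix(assemblages)) {
    if (ncol(assemblages) != length(taxa)) {
      abort("Assemblage matrix does not match the model taxonomy.")
    }
    m <- assemblages
    check_composition(m, "assemblages")
    storage.mode(m) <- "double"
    return(m)
  }
  assemblages <- as_tibble(assemblages)
  missing <- setdiff(taxa, names(assemblages))
  if (length(missing)) {
    abort(paste0("Assemblages lack model taxa: ", paste(missing, collapse = ", ")))
  }
  composition_matrix(assemblages, taxa)
}

#' Analog quality screening for a fossil sequence
#'
#' Flags fossil samples whose squared-chord distance to the closest modern
#' calibration sample exceeds a no-analog threshold (0.25 by convention).
#'
#' @param samples Tibble of fossil assemblages (taxon proportion columns; an
#'   `age` column, if present, is carried through).
#' @param train Calibration tibble.
#' @param threshold No-analog squared-chord distance threshold.
#' @return Tibble with `min_distance` and logical `poor_analog` per sample,
#'   plus attributes `n_flagged` and `fraction_flagged`.
#' @export
analog_quality <- function(samples, train, threshold = 0.25) {
  train <- as_calibration(train, attr(train, "taxa"))
  taxa <- calibration_taxa(train)
  comp <- align_assemblages(samples, taxa)
  D <- chord_distance_matrix(comp, composition_matrix(train, taxa))
  dmin <- apply(D, 1, min)
  out <- tibble(min_distance = dmin, poor_analog = dmin > threshold)
  if (is.data.frame(samples) && "age" %in% names(samples)) {
    out <- dplyr::bind_cols(tibble(age = samples$age), out)
  }
  attr(out, "n_flagged") <- sum(out$poor_analog)
  attr(out, "fraction_flagged") <- mean(out$poor_analog)
  out
}
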