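#' Squared-chord distance between two compositions
#'
#' The canonical pollen dissimilarity `sum((sqrt(p) - sqrt(q))^2)`. On
#' proportion vectors (non-negative, summing to 1) the distance is symmetric
#' and bounded in `[0, 2]`; a value of 0.25 is the conventional threshold
#' separating good from poor modern analogs.
#'
#' @param p,q Numeric composition vectors over the same taxonomy
#'   (non-negative; proportions).
#' @return A single non-negative distance.
#' @export
#' @examples
#' squared_chord_distance(c(0.5, 0.5), c(1, 0))
squared_chord_distance <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must share the same taxonomy (equal length).")
  check_composition(p, "p")
  check_composition(q, "q")
  sum((sqrt(p) - sqrt(q))^2)
}

# All pairwise squared-chord distances between rows of two proportion
# matrices; the workhorse behind MAT prediction and analog screening.
chord_distance_matrix <- function(A, B) {
  sa <- sqrt(A)
  sb <- sqrt(B)
  d2 <- outer(rowSums(A), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B)) -
    2 * tcrossprod(sa, sb)
  pmax(d2, 0)
}

# -- calibration-table conventions -------------------------------------------
# A calibration dataset is an ordinary tibble: metadata/climate columns plus
# one proportion column per pollen taxon, flagged by a "taxa" attribute.

reserved_calibration_cols <- function() {
  c("site_id", "lat", "lon", "tjul", "water_balance", "gdd5")
}

#' Declare the taxon columns of a calibration or fossil table
#'
#' @param data Tibble holding per-row compositions in taxon columns.
#' @param taxa Character vector of taxon column names; if `NULL`, every
#'   column not among the reserved metadata/climate names
#'   (`site_id, lat, lon, tjul, water_balance, gdd5, age`) is taken as a taxon.
#' @return `data` with a `taxa` attribute, rows validated as simplex-valued.
#' @export
as_calibration <- function(data, taxa = NULL) {
  data <- as_tibble(data)
  if (is.null(taxa)) {
    taxa <- setdiff(names(data), c(reserved_calibration_cols(), "age"))
  }
  missing <- setdiff(taxa, names(data))
  if (length(missing)) abort(paste0("Taxon columns not found: ", paste(missing, collapse = ", ")))
  if (!length(taxa)) abort("No taxon columns identified.")
  comp <- composition_matrix(data, taxa)
  rs <- rowSums(comp)
  if (any(abs(rs - 1) > 1e-6)) {
    abort("Compositions must sum to 1 per row (see `read_calibration_table()` for percentage input).")
  }
  attr(data, "taxa") <- taxa
  data
}

#' @rdname as_calibration
#' @export
calibration_taxa <- function(data) {
  taxa <- attr(data, "taxa")
  if (is.null(taxa)) {
    taxa <- setdiff(names(data), c(reserved_calibration_cols(), "age"))
  }
  taxa
}

composition_matrix <- function(data, taxa) {
  m <- as.matrix(data[, taxa, drop = FALSE])
  if (!is.numeric(m)) abort("Taxon columns must be numeric proportions.")
  check_composition(m, "composition")
  storage.mode(m) <- "double"
  m
}
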