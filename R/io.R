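#' Read and write calibration tables
#'
#' Delimited text with a header row: `site_id`, `lat`, `lon`, one column per
#' taxon, and the climate columns (`tjul`, `water_balance`, `gdd5`).
#' Percentage compositions (rows summing to 100 within 1) are normalized to
#' proportions with a warning; negative proportions are a hard error with
#' row/column context.
#'
#' @param path File path (any delimiter `readr` can sniff; write uses CSV).
#' @param taxa Taxon column names; `NULL` infers them as every non-reserved
#'   column.
#' @return A calibration tibble (see [as_calibration()]).
#' @export
read_calibration_table <- function(path, taxa = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(taxa)) taxa <- setdiff(names(data), c(reserved_calibration_cols(), "age"))
  data[taxa] <- normalize_compositions(data[taxa], path)
  as_calibration(data, taxa)
}

#' @rdname read_calibration_table
#' @param data Calibration tibble to write.
#' @export
write_calibration_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

normalize_compositions <- function(comp, context) {
  m <- as.matrix(comp)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("Negative proportion at row %d, column `%s` in %s.",
                  neg[1, 1], colnames(m)[neg[1, 2]], context))
  }
  rs <- rowSums(m)
  pct <- abs(rs - 100) <= 1
  if (any(pct)) {
    warn(sprintf("%d rows sum to ~100; interpreting as percentages and normalizing.", sum(pct)))
    m[pct, ] <- m[pct, ] / rs[pct]
  }
  as_tibble(m)
}

#' Read and write fossil sequence tables
#'
#' Long delimited text with one row per fossil sample: site metadata columns
#' (`site_id`, `lat`, `lon`, `modern_wb`, `n_dates`, `bottom_age`), the
#' sample `age` (cal ka BP), and taxon proportion columns. Reading nests the
#' samples into the one-row-per-site table used by [filter_sites()].
#'
#' @inheritParams read_calibration_table
#' @return Nested site tibble with a `data` list-column.
#' @export
read_fossil_table <- function(path, taxa = NULL) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("site_id", "lat", "lon", "modern_wb", "n_dates", "bottom_age")
  missing <- setdiff(c(meta_cols, "age"), names(long))
  if (length(missing)) {
    abort(paste0("Fossil table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (is.null(taxa)) taxa <- setdiff(names(long), c(meta_cols, "age", "n_samples"))
  long[taxa] <- normalize_compositions(long[taxa], path)
  long %>%
    arrange(.data$site_id, .data$age) %>%
    tidyr::nest(data = all_of(c("age", taxa))) %>%
    mutate(n_samples = vapply(.data$data, nrow, integer(1))) %>%
    select(all_of(meta_cols), "n_samples", "data")
}

#' @rdname read_fossil_table
#' @param sites Nested site tibble to write.
#' @export
write_fossil_table <- function(sites, path) {
  long <- tidyr::unnest(select(sites, !"n_samples"), "data")
  readr::write_csv(long, path)
  invisible(path)
}

#' Read and write gridded field stacks
#'
#' Long delimited text with named dimension columns `lat`, `lon`, `time`, a
#' `value` column, and a logical `land` mask column.
#'
#' @param path File path.
#' @param units,name Metadata attached to the returned field.
#' @return A [grid_field()].
#' @export
read_field_stack <- function(path, units = "", name = "") {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("lat", "lon", "time", "value")
  if (!all(need %in% names(long))) {
    abort(paste0("Field stack needs columns: ", paste(need, collapse = ", ")))
  }
  lats <- sort(unique(long$lat))
  lons <- sort(unique(long$lon))
  times <- sort(unique(long$time))
  if (nrow(long) != length(lats) * length(lons) * length(times)) {
    abort("Field stack is not a complete lat x lon x time grid.")
  }
  long <- arrange(long, .data$time, .data$lon, .data$lat)
  vals <- array(long$value, c(length(lats), length(lons), length(times)))
  mask <- NULL
  if ("land" %in% names(long)) {
    mask <- matrix(as.logical(long$land[seq_len(length(lats) * length(lons))]),
                   length(lats), length(lons))
  }
  grid_field(vals, lats, lons, times, mask, units = units, name = name)
}

#' @rdname read_field_stack
#' @param field `grid_field` to write.
#' @export
write_field_stack <- function(field, path) {
  readr::write_csv(as_tibble(field), path)
  invisible(path)
}
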