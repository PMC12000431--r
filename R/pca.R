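#' Principal-component decomposition of multi-site reconstructions
#'
#' Column-centered PCA (covariance matrix; all sites share mm/a units) of the
#' time-by-site anomaly matrix over a common window. Sites not covering the
#' full window are dropped first. Components are oriented so the mean site
#' loading is non-negative; when longitudes are supplied, the second
#' component is instead oriented so the eastmost-minus-westmost loading
#' contrast is negative (stable display of the east-west moisture mode).
#'
#' @param series Long tibble `(site_id, age, anomaly)` of aligned site series.
#' @param window Analysis window `(young, old)`, cal ka BP (default 0.25-11).
#' @param site_lon Optional named vector of site longitudes used for the PC2
#'   sign convention.
#' @return A `recon_pca` object with eigenvalues, variance fractions, site
#'   loadings and time scores (`tidy()` for loadings, `glance()` for the
#'   variance summary).
#' @export
pca_reconstructions <- function(series, window = c(0.25, 11), site_lon = NULL) {
  if (!all(c("site_id", "age", "anomaly") %in% names(series))) {
    abort("`series` needs columns site_id, age, anomaly.")
  }
  sub <- filter(series, .data$age >= window[1], .data$age <= window[2])
  wide <- tidyr::pivot_wider(sub, id_cols = "age", names_from = "site_id",
                             values_from = "anomaly")
  wide <- arrange(wide, .data$age)
  keep <- names(wide)[-1][colSums(is.na(wide[, -1])) == 0]
  if (length(keep) < 2) abort("Fewer than 2 sites cover the analysis window.")
  M <- as.matrix(wide[, keep])
  if (anyNA(M)) abort("Missing cells inside the analysis window.")
  p <- prcomp(M, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  k <- ncol(p$rotation)
  # sign conventions for display stability
  for (j in seq_len(k)) {
    flip <- FALSE
    if (j == 2 && !is.null(site_lon) && all(keep %in% names(site_lon))) {
      lon <- site_lon[keep]
      contrast <- p$rotation[which.max(lon), j] - p$rotation[which.min(lon), j]
      flip <- contrast > 0
    } else {
      flip <- mean(p$rotation[, j]) < 0
    }
    if (flip) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(
    list(
      eigenvalues = eig,
      variance_fraction = eig / sum(eig),
      loadings = dplyr::bind_cols(tibble(site_id = keep),
                                  as_tibble(p$rotation)),
      scores = dplyr::bind_cols(tibble(age = wide$age), as_tibble(p$x)),
      total_variance = sum(eig),
      window = window
    ),
    class = "recon_pca"
  )
}

#' @export
print.recon_pca <- function(x, ...) {
  cat(sprintf("PCA of %d site reconstructions over %g-%g ka\n",
              nrow(x$loadings), x$window[1], x$window[2]))
  vf <- round(100 * x$variance_fraction[seq_len(min(4, length(x$variance_fraction)))], 1)
  cat("Variance explained (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

#' @export
tidy.recon_pca <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  x[[matrix]]
}

#' @export
glance.recon_pca <- function(x, ...) {
  tibble(
    n_sites = nrow(x$loadings),
    n_steps = nrow(x$scores),
    pc1_variance = x$variance_fraction[1],
    pc2_variance = x$variance_fraction[2],
    total_variance = x$total_variance
  )
}

#' @export
autoplot.recon_pca <- function(object, n_components = 2, ...) {
  sc <- tidyr::pivot_longer(object$scores,
                            cols = paste0("PC", seq_len(n_components)),
                            names_to = "component", values_to = "score")
  ggplot2::ggplot(sc, ggplot2::aes(.data$age, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (cal ka BP)", y = "score")
}
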