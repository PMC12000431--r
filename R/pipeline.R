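#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects generator sizes, transfer-function settings and stage toggles for
#' [run_pipeline()]. Defaults give a small but complete synthetic study:
#' calibration set, three regions of fossil sequences from a planted drought
#' trajectory, MAT and BRT reconstructions, bootstrap synthesis, SiZer map,
#' PCA, wavelet summary and field-coupling CCA.
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param n_calibration_sites Calibration sample size.
#' @param n_sites_per_region Fossil sequences per region.
#' @param regions Region labels.
#' @param method Transfer function for the reconstructions (`"MAT"`/`"BRT"`).
#' @param brt_max_trees,brt_cv_folds BRT settings used when `method = "BRT"`.
#' @param n_boot Bootstrap replicates for the synthesis.
#' @param stages Stages to run, in dependency order.
#' @param n_field_years Length of the synthetic coupled fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_calibration_sites = 400,
                            n_sites_per_region = 5,
                            regions = c("MW", "GL", "NE"),
                            method = c("MAT", "BRT"),
                            brt_max_trees = 500, brt_cv_folds = 5,
                            n_boot = 1000,
                            stages = c("simulate", "fit", "reconstruct",
                                       "synthesize", "trends", "spectra", "cca"),
                            n_field_years = 150) {
  method <- match.arg(method)
  structure(
    list(seed = seed, n_calibration_sites = n_calibration_sites,
         n_sites_per_region = n_sites_per_region, regions = regions,
         method = method, brt_max_trees = brt_max_trees,
         brt_cv_folds = brt_cv_folds, n_boot = n_boot, stages = stages,
         n_field_years = n_field_years),
    class = "pipeline_config"
  )
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs as delimited text under `out_dir` together with a JSON manifest
#' (inputs, seeds, parameter values, package version). Reruns with the same
#' configuration produce identical numeric outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + seq_len(20)
  res <- list()
  stage_of <- function(s) s %in% config$stages
  taxa <- default_taxa()

  run_stage <- function(name, expr) {
    message(sprintf("[paleowb] stage %-11s ...", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  if (stage_of("simulate")) {
    res$calibration <- run_stage("simulate", {
      generate_calibration_dataset(config$n_calibration_sites, taxa,
                                   seed = seeds[1])
    })
    write_calibration_table(res$calibration, file.path(out_dir, "calibration.csv"))
    amp <- setNames(c(-110, -100, -180), c("MW", "GL", "NE"))
    ctr <- setNames(c(7, 8, 10.5), c("MW", "GL", "NE"))
    res$sites <- purrr::map_dfr(seq_along(config$regions), function(r) {
      region <- config$regions[r]
      traj <- drought_trajectory(amplitude = amp[[region]], center = ctr[[region]],
                                 span = c(0, 11))
      purrr::map_dfr(seq_len(config$n_sites_per_region), function(i) {
        generate_fossil_sequence(
          traj, taxa, seed = seeds[2] + 100 * r + i,
          site_id = sprintf("%s%02d", region, i),
          lat = 44 + r + 0.3 * i, lon = -98 + 10 * r + 0.5 * i,
          n_dates = 10
        ) %>% mutate(region = region)
      })
    })
    write_fossil_table(select(res$sites, !"region"), file.path(out_dir, "fossil_samples.csv"))
  }

  if (stage_of("fit")) {
    res$model <- run_stage("fit", {
      if (config$method == "BRT") {
        brt_fit(res$calibration, "water_balance",
                max_trees = config$brt_max_trees,
                cv_folds = config$brt_cv_folds, seed = seeds[3])
      } else {
        mat_fit(res$calibration, "water_balance")
      }
    })
  }

  if (stage_of("reconstruct")) {
    res$filtered <- run_stage("reconstruct", filter_sites(res$sites))
    accepted <- filter(res$filtered, .data$accepted)
    res$reconstructions <- reconstruct_sequences(accepted, res$model) %>%
      left_join(select(res$filtered, "site_id", "region"), by = "site_id")
    readr::write_csv(res$reconstructions, file.path(out_dir, "reconstructions.csv"))
  }

  if (stage_of("synthesize")) {
    res$synthesis <- run_stage("synthesize", {
      res$reconstructions %>%
        group_by(.data$region, .data$site_id) %>%
        dplyr::group_modify(~align_and_interpolate(.x)) %>%
        ungroup() %>%
        tidyr::nest(.by = "region") %>%
        mutate(synthesis = purrr::map(.data$data, regional_synthesis,
                                      n_boot = config$n_boot, seed = seeds[4])) %>%
        select(!"data")
    })
    purrr::walk2(res$synthesis$region, res$synthesis$synthesis, function(r, s) {
      readr::write_csv(s, file.path(out_dir, sprintf("synthesis_%s.csv", r)))
    })
  }

  if (stage_of("trends")) {
    run_stage("trends", {
      res$sizer <- purrr::map(setNames(res$synthesis$synthesis, res$synthesis$region),
                              function(s) sizer_map(s))
      purrr::iwalk(res$sizer, function(sz, r) {
        readr::write_csv(tidy(sz), file.path(out_dir, sprintf("sizer_%s.csv", r)))
      })
      long <- res$reconstructions %>%
        group_by(.data$site_id) %>%
        dplyr::group_modify(~align_and_interpolate(.x)) %>%
        ungroup()
      res$pca <- pca_reconstructions(long)
      readr::write_csv(tidy(res$pca), file.path(out_dir, "pca_loadings.csv"))
      readr::write_csv(tidy(res$pca, "scores"), file.path(out_dir, "pca_scores.csv"))
    })
  }

  if (stage_of("spectra")) {
    run_stage("spectra", {
      res$periods <- purrr::map_dfr(seq_len(nrow(res$synthesis)), function(i) {
        s <- res$synthesis$synthesis[[i]]
        ser <- tibble(time = s$age, value = s$mean) %>%
          filter(is.finite(.data$value))
        filt <- preprocess_series(ser, highpass_cutoff = 1)
        wr <- morlet_wavelet(filt)
        extract_significant_periods(wr) %>%
          mutate(group = res$synthesis$region[i])
      })
      if (nrow(res$periods)) {
        res$period_kde <- periodicity_kde(res$periods)
        readr::write_csv(res$periods, file.path(out_dir, "significant_periods.csv"))
        readr::write_csv(res$period_kde, file.path(out_dir, "period_kde.csv"))
      }
    })
  }

  if (stage_of("cca")) {
    run_stage("cca", {
      pat <- dipole_pattern(12, 16)
      fields <- generate_coupled_fields(
        n_years = config$n_field_years,
        modes = list(list(slp_pattern = pat, wb_pattern = pat, coupling_r = 0.8,
                          amplitude = 3)),
        seed = seeds[5]
      )
      res$cca <- cca(eof_truncate(fields$slp), eof_truncate(fields$wb),
                      n_perm = 199, seed = seeds[6])
      readr::write_csv(tidy(res$cca), file.path(out_dir, "cca_summary.csv"))
    })
  }

  manifest <- list(
    package = "paleowb",
    version = as.character(utils::packageVersion("paleowb")),
    seed = config$seed,
    stage_seeds = seeds,
    stages = config$stages,
    parameters = config[setdiff(names(config), "stages")],
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
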