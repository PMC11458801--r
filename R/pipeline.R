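# End-to-end orchestration: cell-image quantification, scattering-series
# evaluation, named fixture scenarios and a small command-line interface.

#' Run the cell-image quantification pipeline
#'
#' For each scene: classify pixels (with automatic nucleolus masking),
#' measure the aggregate area fraction of the cytoplasm and the
#' stress-granule colocalization, then summarize across cells. All stages
#' are deterministic given their inputs.
#'
#' @param scenes list of generated scenes (as from [generate_cell_image()]),
#'   or a list with elements `image` and `rois` loaded from disk.
#' @param params a [classifier_params()].
#' @param group optional group label per scene for the summary.
#' @param out_dir optional directory; when given, per-cell and summary CSVs
#'   plus a config manifest are written there.
#' @return list with `per_cell` (data.frame: `cell_id`, `aggregate_area_pct`,
#'   `monomer_mean`, `n_granules`, `granule_monomer_enrichment`),
#'   `colocalization` (row-bound per-granule tables), `mean_pct`, `sd_pct`,
#'   `pooled_pct` (pooled-pixel variant).
#' @export
run_cell_analysis <- function(scenes, params = classifier_params(),
                              group = NULL, out_dir = NULL) {
  if (length(scenes) == 0L) stopf("no scenes supplied")
  per_cell <- NULL
  coloc_all <- NULL
  agg_px <- 0; cyt_px <- 0
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stopf("cell %d, stage %s: %s", i, what, conditionMessage(e)))
    }
    nucleoli <- stage("mask_nucleoli",
                      mask_nucleoli(sc$image, sc$rois$nucleus))
    cm <- stage("classify_pixels",
                classify_pixels(sc$image, params, exclude = nucleoli))
    pct <- stage("aggregate_area_fraction",
                 aggregate_area_fraction(cm, sc$rois$cytoplasm))
    coloc <- stage("colocalize_with_granules",
                   colocalize_with_granules(cm, sc$image, sc$rois$granules,
                                            sc$rois$cytoplasm))
    mono <- monomer_channel(sc$image)
    per_cell <- rbind(per_cell, data.frame(
      cell_id = i,
      aggregate_area_pct = pct,
      monomer_mean = mean(mono[sc$rois$cytoplasm]),
      n_granules = nrow(coloc),
      granule_monomer_enrichment =
        if (nrow(coloc)) mean(coloc$monomer_enrichment) else NA_real_))
    if (nrow(coloc)) coloc_all <- rbind(coloc_all, cbind(cell_id = i, coloc))
    agg_px <- agg_px + sum(cm == 2L & sc$rois$cytoplasm)
    cyt_px <- cyt_px + sum(sc$rois$cytoplasm)
  }
  out <- list(per_cell = per_cell,
              colocalization = coloc_all %||%
                data.frame(cell_id = integer(0)),
              mean_pct = mean(per_cell$aggregate_area_pct),
              sd_pct = stats::sd(per_cell$aggregate_area_pct),
              pooled_pct = 100 * agg_px / cyt_px)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_cell, file.path(out_dir, "per_cell.csv"),
                     row.names = FALSE)
    utils::write.csv(out$colocalization,
                     file.path(out_dir, "colocalization.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(params = unclass(params), n_cells = length(scenes),
           mean_pct = out$mean_pct, sd_pct = out$sd_pct,
           pooled_pct = out$pooled_pct),
      file.path(out_dir, "cell_analysis_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Run the scattering-series evaluation pipeline
#'
#' Full evaluation chain per frame plus induction-time detection; when a
#' second series is given, the two induction times are compared against the
#' frame resolution.
#'
#' @param series a `scattering_series`.
#' @param calib an [ls_calibration()] (defaults to the series' own).
#' @param series_b optional second series (e.g. an additive condition).
#' @param out_dir optional output directory for the results CSV + manifest.
#' @return the [analyze_series()] result, with (when `series_b` is given)
#'   elements `induction_b`, `induction_difference_s` and
#'   `differs_beyond_resolution` added.
#' @export
run_ls_analysis <- function(series, calib = NULL, series_b = NULL,
                            out_dir = NULL) {
  res <- analyze_series(series, calib)
  if (!is.null(series_b)) {
    res_b <- analyze_series(series_b, calib)
    dt <- stats::median(diff(vapply(series$frames, `[[`, numeric(1), "t")))
    res$induction_b <- res_b$induction_time_s
    res$induction_difference_s <- res_b$induction_time_s - res$induction_time_s
    res$differs_beyond_resolution <-
      isTRUE(abs(res$induction_difference_s) > 2 * dt)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$results, file.path(out_dir, "ls_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(induction_time_s = res$induction_time_s,
           baseline_Mw = res$baseline_Mw, baseline_sd = res$baseline_sd),
      file.path(out_dir, "ls_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

# Named generator scenarios with the study's planted conditions.
fixture_scenarios <- function() {
  list(
    `unstressed-cells` = function(seed) {
      lapply(seq_len(5L), function(i)
        generate_cell_image(cell_scene(
          planted_aggregate_fraction = 0.40, n_granules = 0L,
          seed = seed + i)))
    },
    `stressed-cells` = function(seed) {
      lapply(seq_len(5L), function(i)
        generate_cell_image(cell_scene(
          planted_aggregate_fraction = 0, n_granules = 3L,
          seed = seed + i)))
    },
    `droplet-growth` = function(seed) {
      generate_scattering_series(
        droplet_growth_model(), ls_calibration(rr_std = 1.35e-5),
        n_frames = 90L, noise = 0.01, seed = seed)
    },
    frap = function(seed) {
      lapply(seq_len(6L), function(i)
        generate_frap_trace(I0 = 0.6, a = 0.6, beta = 0.1,
                            t_grid = seq(-10, 120, by = 1),
                            noise_sd = 0.02, seed = seed + i))
    },
    `ficoll-ramp` = function(seed) {
      # non-monotone T_JA(condition) profile: rises to 2.5 wt%, then falls
      conds <- c(0, 2.5, 5, 10, 22.5)
      tja <- c(21.5, 23.0, 22.0, 21.0, 19.5)
      ramps <- list()
      labels <- numeric(0)
      for (k in seq_along(conds)) {
        for (rep in 1:2) {
          ramps[[length(ramps) + 1L]] <- generate_absorbance_ramp(
            T_JA_true = tja[k], T_grid = seq(25, 18, by = -0.5),
            seed = seed + 100 * k + rep)
          labels <- c(labels, conds[k])
        }
      }
      list(ramps = ramps, conditions = labels, truth = data.frame(
        condition = conds, T_JA_true = tja))
    }
  )
}

#' Generate a named fixture dataset
#'
#' Writes the generator outputs of a named scenario, the ground-truth
#' sidecars and a manifest to `dir`. Same scenario and seed always produce
#' identical bytes.
#'
#' @param scenario one of `"unstressed-cells"`, `"stressed-cells"`,
#'   `"droplet-growth"`, `"frap"`, `"ficoll-ramp"`.
#' @param seed integer RNG seed.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
make_fixtures <- function(scenario, seed, dir) {
  scen <- fixture_scenarios()
  if (!scenario %in% names(scen))
    stopf("unknown scenario '%s'; available: %s", scenario,
          paste(names(scen), collapse = ", "))
  obj <- scen[[scenario]](as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scenario = scenario, seed = as.integer(seed))
  if (scenario %in% c("unstressed-cells", "stressed-cells")) {
    for (i in seq_along(obj)) {
      sub <- file.path(dir, sprintf("cell%02d", i))
      write_spectral_image(obj[[i]]$image, sub)
      write_matrix_csv(obj[[i]]$truth, file.path(sub, "truth_classmap.csv"))
      write_matrix_csv(obj[[i]]$rois$cytoplasm * 1L,
                       file.path(sub, "roi_cytoplasm.csv"))
      write_matrix_csv(obj[[i]]$rois$nucleus * 1L,
                       file.path(sub, "roi_nucleus.csv"))
      write_matrix_csv(obj[[i]]$rois$granules,
                       file.path(sub, "roi_granules.csv"))
    }
    manifest$n_cells <- length(obj)
    manifest$planted_fraction <- vapply(obj, `[[`, numeric(1), "planted_fraction")
  } else if (scenario == "droplet-growth") {
    write_scattering_frames(obj, dir)
    manifest$truth <- list(
      nucleation_time_s = obj$truth$model$nucleation_time,
      radius_max_nm = obj$truth$model$radius_max,
      baseline_Mw = obj$truth$model$baseline_Mw)
  } else if (scenario == "frap") {
    for (i in seq_along(obj)) {
      write_frap_trace(obj[[i]], file.path(dir, sprintf("frap%02d.csv", i)))
    }
    manifest$truth <- list(I0 = attr(obj[[1]], "I0"), a = attr(obj[[1]], "a"),
                           beta = attr(obj[[1]], "beta"))
  } else if (scenario == "ficoll-ramp") {
    for (i in seq_along(obj$ramps)) {
      write_absorbance_ramp(obj$ramps[[i]],
                            file.path(dir, sprintf("ramp%02d.csv", i)))
    }
    utils::write.csv(data.frame(ramp = seq_along(obj$ramps),
                                condition = obj$conditions),
                     file.path(dir, "conditions.csv"), row.names = FALSE)
    utils::write.csv(obj$truth, file.path(dir, "truth_T_JA.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Minimal CLI: `picquant_cli(c("simulate", "--scenario", "droplet-growth",
#' "--seed", "1", "--out", "fixtures/"))`. Subcommands: `simulate`
#' (fixtures), `ls` (scattering evaluation of a fixture directory), `uvvis`
#' (ramp threshold detection on a ramp CSV). Intended for
#' `Rscript -e 'picquant::picquant_cli()'` use.
#'
#' @param args character vector; defaults to `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
picquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  sub <- if (length(args)) args[1L] else ""
  if (sub == "simulate") {
    make_fixtures(get_opt("--scenario", "droplet-growth"),
                  as.integer(get_opt("--seed", "1")),
                  get_opt("--out", "fixtures"))
  } else if (sub == "ls") {
    series <- read_scattering_frames(get_opt("--in", "fixtures"))
    res <- run_ls_analysis(series, out_dir = get_opt("--out", "results"))
    cat(sprintf("induction time: %s s\n", format(res$induction_time_s)))
  } else if (sub == "uvvis") {
    ramp <- read_absorbance_ramp(get_opt("--in", "ramp.csv"))
    det <- detect_peak_onset(ramp)
    cat(sprintf("T_JA: %s C (censoring: %s)\n", format(det$T_JA), det$censored))
  } else {
    cat("usage: picquant_cli <simulate|ls|uvvis> [--scenario S] [--seed N] [--in DIR] [--out DIR]\n")
    return(invisible(1L))
  }
  invisible(0L)
}
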