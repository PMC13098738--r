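#' Load a pipeline configuration
#'
#' Single YAML schema with optional `simulate`, `process`, `stats` and
#' `synth` sections; see the individual `run_*` functions for the fields
#' each consumes.
#'
#' @param path YAML config path.
#' @return Named list of sections.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

# one manifest per run: config hash, seeds, package version, output digests
.write_manifest <- function(out_dir, command, config, seed, outputs) {
  tf <- tempfile(); on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  manifest <- list(
    command = command,
    config_md5 = unname(tools::md5sum(tf)),
    seed = seed,
    package_version = as.character(packageVersion("slimr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the Monte Carlo simulation study
#'
#' Builds the baseline model (bundled four-layer skin unless
#' `config$model_file` points elsewhere), applies the dermal scattering
#' perturbation, simulates both models at every wavelength, applies each
#' melanin level by perturbation-MC reweighting, and writes per-level
#' reflectance-difference tables, the per-wavelength optimal spatial
#' frequencies, depth (zmax) statistics with per-layer contributions at a
#' focus cell, and a run manifest.
#'
#' Config fields (all optional): `model_file`, `wavelengths`,
#' `spatial_frequencies`, `n_photons`, `melanin_levels`,
#' `perturbation_factor`, `focus_wavelength`, `focus_fx`.
#'
#' @param config list (a `simulate` config section).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all simulations.
#' @return Invisibly, a list with the `delta_rd_grid`s per melanin level
#'   and the optimal-fx table.
#' @export
run_simulation_study <- function(config = list(), out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wls <- config$wavelengths %||% c(691, 731, 811, 851)
  fxs <- config$spatial_frequencies %||% c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
  n_photons <- config$n_photons %||% 1e6
  levels <- config$melanin_levels %||% c(0.02, 0.05, 0.10)
  factor <- config$perturbation_factor %||% 0.8
  base <- if (!is.null(config$model_file))
    load_tissue_model(config$model_file, wavelengths = wls)
  else skin_model(wavelengths = wls)
  pert <- apply_scleroderma_perturbation(base, factor)
  outputs <- character()
  grids <- list()
  opt_rows <- list()
  for (lev in levels) {
    g <- delta_rd_grid(base, pert, wls, fxs, n_photons = n_photons,
                       seed = seed, melanin_level = lev)
    grids[[as.character(lev)]] <- g
    df <- expand.grid(wavelength = wls, fx = fxs)
    df$rd_baseline <- as.vector(g$rd_baseline)
    df$rd_perturbed <- as.vector(g$rd_perturbed)
    df$delta_rd <- as.vector(g$delta_rd)
    df$se <- as.vector(g$mc_standard_error)
    f <- file.path(out_dir, sprintf("delta_rd_melanin_%02d.csv", round(100 * lev)))
    write.csv(df, f, row.names = FALSE)
    outputs <- c(outputs, f)
    opt <- optimal_fx(g)
    opt_rows[[as.character(lev)]] <- data.frame(
      melanin_level = lev, wavelength = as.numeric(names(opt)),
      optimal_fx = as.numeric(opt))
  }
  opt_tab <- do.call(rbind, opt_rows)
  f_opt <- file.path(out_dir, "optimal_fx.csv")
  write.csv(opt_tab, f_opt, row.names = FALSE)
  outputs <- c(outputs, f_opt)

  # depth statistics at the focus cell (defaults: 851 nm, 0.15 mm^-1)
  fw <- config$focus_wavelength %||% wls[length(wls)]
  ff <- config$focus_fx %||% fxs[min(5, length(fxs))]
  t_b <- simulate_pencil_beam(base, fw, n_photons, seed)
  t_p <- simulate_pencil_beam(pert, fw, n_photons, seed)
  dmua <- levels[1] * melanosome_mua(fw)
  d_b <- pzmax_distribution(pmc_reweight(t_b, "epidermis", dmua), ff)
  d_p <- pzmax_distribution(pmc_reweight(t_p, "epidermis", dmua), ff)
  pz <- data.frame(z_mm = (d_b$z_edges[-1] + d_b$z_edges[-length(d_b$z_edges)]) / 2,
                   pzmax_baseline = d_b$pzmax, pzmax_perturbed = d_p$pzmax,
                   diff = d_p$pzmax - d_b$pzmax)
  f_pz <- file.path(out_dir, sprintf("pzmax_%dnm_fx%03d.csv", fw, round(1000 * ff)))
  write.csv(pz, f_pz, row.names = FALSE)
  contrib <- layer_contributions(d_b, d_p, base)
  f_lc <- file.path(out_dir, "layer_contributions.csv")
  write.csv(data.frame(layer = names(contrib), delta_rd_contribution = contrib),
            f_lc, row.names = FALSE)
  outputs <- c(outputs, f_pz, f_lc)
  .write_manifest(out_dir, "simulate", config, seed, outputs)
  invisible(list(grids = grids, optimal_fx = opt_tab,
                 layer_contributions = contrib))
}

#' Run the image-processing pipeline to a cohort table
#'
#' For every entry of `config$measurements` (fields: `subject_id`,
#' `group`, `site`, optionally `race`, `stack_prefix`, `roi` with
#' `site`/`origin`/optional size, optionally a list of finger `rois`),
#' reads the phase stack and the matching phantom stack
#' (`config$phantoms`, keyed `"<wavelength>_<fx>"`, each with
#' `stack_prefix` and `rd_model`), demodulates both, calibrates, applies
#' an optional correction field (TIFF path in `correction_file`), takes
#' ROI means, and appends rows to the cohort CSV.
#'
#' @param config list (a `process` config section).
#' @param out_dir output directory.
#' @return Invisibly, the cohort data frame (also written to
#'   `cohort.csv`).
#' @export
run_processing <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phantoms <- config$phantoms
  if (is.null(phantoms)) stop("config$phantoms is required")
  phantom_amp <- list()
  rows <- list()
  for (m in config$measurements) {
    stack <- read_phase_stack(m$stack_prefix)
    key <- sprintf("%s_%s", format(stack$wavelength), format(stack$spatial_frequency))
    ph <- phantoms[[key]]
    if (is.null(ph))
      stop("no phantom configured for wavelength ", stack$wavelength,
           " nm, fx ", stack$spatial_frequency, " mm^-1")
    if (is.null(phantom_amp[[key]]))
      phantom_amp[[key]] <- demodulate(read_phase_stack(ph$stack_prefix))
    amp <- demodulate(stack)
    map <- calibrate(amp, phantom_amp[[key]], ph$rd_model,
                     wavelength = stack$wavelength,
                     spatial_frequency = stack$spatial_frequency,
                     pixel_pitch = stack$pixel_pitch,
                     calibration_id = key)
    if (!is.null(m$correction_file)) {
      sc <- 1
      side <- paste0(m$correction_file, ".json")
      if (file.exists(side))
        sc <- jsonlite::read_json(side, simplifyVector = TRUE)$intensity_scale %||% 1
      map <- apply_correction(map, .read_float_tiff(m$correction_file, sc))
    }
    rois <- if (!is.null(m$rois)) {
      lapply(m$rois, function(r)
        roi_spec(r$site, unlist(r$origin), r$height, r$width))
    } else {
      r <- m$roi
      list(roi_spec(r$site, unlist(r$origin), r$height, r$width))
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = m$subject_id, group = m$group,
      race = m$race %||% NA_character_, site = m$site,
      wavelength = stack$wavelength,
      spatial_frequency = stack$spatial_frequency,
      mean_rd = roi_mean(map, rois),
      mrss = m$mrss %||% NA_integer_)
  }
  cohort <- do.call(rbind, rows)
  f <- file.path(out_dir, "cohort.csv")
  write.csv(cohort, f, row.names = FALSE)
  .write_manifest(out_dir, "process", config, NA, f)
  invisible(cohort)
}

#' Run the cohort statistics
#'
#' Builds the requested statistic heatmap(s) from a cohort CSV or data
#' frame and writes them (plus the argmax cells) per stratum.
#'
#' @param cohort cohort CSV path or data frame.
#' @param out_dir output directory.
#' @param statistic `"auc"` or `"spearman"`.
#' @param strata character vector of strata (`"all"` and/or race labels).
#' @return Invisibly, the list of `heatmap_grid`s.
#' @export
run_stats <- function(cohort, out_dir, statistic = "auc", strata = "all") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(cohort)) cohort <- read.csv(cohort)
  cohort <- cohort_table(cohort)
  outputs <- character(); grids <- list()
  for (s in strata) {
    g <- build_heatmaps(cohort, statistic, stratum = s)
    grids[[s]] <- g
    f <- file.path(out_dir, sprintf("heatmap_%s_%s.csv", statistic, tolower(s)))
    write.csv(g$values, f)
    fj <- file.path(out_dir, sprintf("argmax_%s_%s.json", statistic, tolower(s)))
    jsonlite::write_json(g$argmax, fj, digits = NA)
    outputs <- c(outputs, f, fj)
  }
  .write_manifest(out_dir, "stats", list(statistic = statistic, strata = strata),
                  NA, outputs)
  invisible(grids)
}

#' Generate synthetic fixtures on disk
#'
#' Writes synthetic phase stacks (sample + phantom sharing the instrument
#' response; ground truth next to the outputs with a `_truth` suffix) and
#' a synthetic cohort CSV in exactly the formats the processing and
#' statistics stages read.
#'
#' Config fields: `images` (list of specs with `name`, `true_rd`,
#' `wavelength`, `spatial_frequency`, `dims`, `noise_sd`, ...) and
#' `cohort` (arguments of [gen_cohort()]).
#'
#' @param config list (a `synth` config section).
#' @param out_dir output directory.
#' @param seed integer master seed; per-output seeds are derived as
#'   `seed + index`.
#' @return Invisibly, NULL.
#' @export
run_synth <- function(config, out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  for (i in seq_along(config$images)) {
    sp <- config$images[[i]]
    gen <- gen_phase_stack(sp$true_rd, sp$spatial_frequency, sp$wavelength,
                           dims = unlist(sp$dims %||% c(64, 64)),
                           noise_sd = sp$noise_sd %||% 0,
                           seed = seed + i)
    prefix <- file.path(out_dir, sp$name)
    write_phase_stack(gen$stack, prefix)
    jsonlite::write_json(gen$truth[c("dc_offset", "modulation_scale",
                                     "noise_sd", "seed", "n_clipped")],
                         paste0(prefix, "_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    .write_float_tiff(gen$truth$true_rd, paste0(prefix, "_truth.tif"))
    outputs <- c(outputs, paste0(prefix, ".json"))
  }
  if (!is.null(config$cohort)) {
    args <- config$cohort
    args$seed <- args$seed %||% seed
    cohort <- do.call(gen_cohort, args)
    f <- file.path(out_dir, "synthetic_cohort.csv")
    write.csv(cohort, f, row.names = FALSE)
    truth <- attr(cohort, "truth")
    jsonlite::write_json(truth[c("effect_cell", "effect_size_d",
                                 "rd_mean_control", "rd_sd",
                                 "site_correlation", "mislabel_prob", "seed")],
                         file.path(out_dir, "synthetic_cohort_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
  }
  .write_manifest(out_dir, "synth", config, seed, outputs)
  invisible(NULL)
}
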