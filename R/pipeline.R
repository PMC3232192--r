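default_config <- function() {
  list(
    seed = 1L,
    output_dir = "results",
    lattice = list(n_pf = 5L, lateral_spacing_nm = 4.6, axial_stagger_nm = 0.88,
                   dimer_rise_nm = 8.8, pf_diameter_nm = 4.0,
                   lattice_type = "B", tube_length_nm = 52.8),
    imaging = list(voxel_size_nm = 0.3, kernel_sigma_nm = 1.2,
                   kernel = "gaussian",
                   tilt_min_deg = -60, tilt_max_deg = 60, tilt_step_deg = 1,
                   defocus_um = 10, voltage_kV = 300, cs_mm = 2.0,
                   amplitude_contrast = 0.07, apply_ctf = TRUE,
                   resample_factor = 1L, snr = Inf),
    recon = list(method = "wedge", wedge_half_angle_deg = 60,
                 rolloff_frac = 0.9),
    analysis = list(rotations_deg = seq(0, 72, by = 9),
                    tilt_axis_angles_deg = c(0, 25, 50, 75),
                    candidates_n_pf = c(4L, 5L, 6L),
                    repeat_band_invnm = c(0.1, 1 / 3)),
    subtomo = list(spacing_nm = 9, box_nm = 12, rotation_limit_deg = 15,
                   translation_limit_nm = 1, n_subvolumes = 25L, snr = 0.5)
  )
}

check_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra) > 0)
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" in ", path) else "",
                 paste(extra, collapse = ", ")))
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_keys(as.list(x[[k]]), ref[[k]], paste0(path, if (nzchar(path)) "$" else "", k))
  }
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()]. Defaults are
#' the published simulation conditions wherever the publication states
#' them (4.6 nm spacing, 0.88 nm stagger, 8.8 nm dimer repeat, +/-60
#' degree tilts in 1 degree steps, 10 um underfocus) plus the package's
#' own documented choices (0.3 nm working voxel, Cs 2.0 mm, 7% amplitude
#' contrast). Unknown keys are rejected. Configurations round-trip through
#' YAML via [read_config()] / [write_config()].
#'
#' @param overrides nested list of values overriding the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- default_config()
  check_keys(overrides, base)
  structure(merge_config(base, overrides), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  clean <- rapply(unclass(config), function(x) {
    if (is.numeric(x) && any(!is.finite(x))) as.character(x) else x
  }, how = "replace")
  yaml::write_yaml(clean, path)
  invisible(path)
}

preset_overrides <- function(preset) {
  switch(preset,
    "fig-3h" = list(imaging = list(voxel_size_nm = 0.24, kernel = "sphere",
                                   resample_factor = 4L),
                    recon = list(method = "wbp"),
                    lattice = list(tube_length_nm = 17.6)),
    "fig-s7" = list(imaging = list(voxel_size_nm = 0.5),
                    lattice = list(tube_length_nm = 35.2)),
    "fig-5" = list(imaging = list(voxel_size_nm = 0.4),
                   lattice = list(tube_length_nm = 70.4)),
    "fig-s8" = list(imaging = list(voxel_size_nm = 0.5),
                    lattice = list(tube_length_nm = 70.4)),
    stop(sprintf("unknown preset '%s' (use fig-3h, fig-s7, fig-5 or fig-s8)", preset))
  )
}

spec_from_config <- function(config) {
  la <- config$lattice
  tube_lattice_spec(n_pf = la$n_pf, lateral_spacing_nm = la$lateral_spacing_nm,
                    axial_stagger_nm = la$axial_stagger_nm,
                    dimer_rise_nm = la$dimer_rise_nm,
                    pf_diameter_nm = la$pf_diameter_nm,
                    lattice_type = la$lattice_type,
                    tube_length_nm = la$tube_length_nm)
}

## Simulate one cross-section through the full published imaging chain:
## fine-voxel map -> tilt-series projection -> CTF -> Fourier resampling to
## the display pixel -> weighted backprojection. Contrast is negated after
## reconstruction (underfocus phase contrast renders protein dark) so wall
## peaks read positive.
simulate_fig3h_section <- function(spec, geom, im, recon, slab_nm) {
  model <- orient_model(build_tube(spec), geom)
  vox <- im$voxel_size_nm
  fac <- max(1L, as.integer(im$resample_factor))
  wall <- 2 * (model$ring_radius_nm + spec$pf_diameter_nm) +
    6 * im$kernel_sigma_nm
  ext <- max(abs(range(c(model$placements$x, model$placements$y)))) * 2 +
    6 * im$kernel_sigma_nm + 2
  ## round the box so grid dimensions divide the resampling factor
  snap <- function(b) vox * 2 * fac * ceiling(b / (vox * 2 * fac))
  map <- rasterize(model, vox, box_nm = c(snap(ext), snap(ext), snap(2 * wall)),
                   kernel_sigma_nm = im$kernel_sigma_nm, kernel = im$kernel)
  if (recon$method == "wedge") {
    tomo <- wedge_tomogram(map, recon$wedge_half_angle_deg)
  } else {
    ts <- project_tilt_series(map, geom)
    if (isTRUE(im$apply_ctf))
      ts <- apply_ctf(ts, ctf_params(im$defocus_um, im$voltage_kV, im$cs_mm,
                                     im$amplitude_contrast))
    if (fac > 1) ts <- resample_series(ts, fac)
    tomo <- weighted_backprojection(ts, thickness_voxels = dim(ts$images)[1],
                                    rolloff_frac = recon$rolloff_frac)
    if (isTRUE(im$apply_ctf)) tomo$data <- -tomo$data
  }
  list(section = extract_cross_section(tomo,
                                       axis = list(point = c(0, 0, 0),
                                                   direction = model$axis_lab),
                                       slab_nm = slab_nm),
       model = model)
}

run_stage_fig3h <- function(config, outdir) {
  spec <- spec_from_config(config)
  im <- config$imaging
  rows <- list()
  for (ang in config$analysis$tilt_axis_angles_deg) {
    geom <- tilt_geometry(im$tilt_min_deg, im$tilt_max_deg, im$tilt_step_deg,
                          angle_to_tilt_axis_deg = ang)
    sim <- simulate_fig3h_section(spec, geom, im, config$recon, slab_nm = 11)
    sec <- sim$section
    pk <- wall_peak_intensities(sec, sim$model$ring_radius_nm)
    write_mrc(sec$data, file.path(outdir, sprintf("fig3h_section_%02d.mrc", ang)),
              voxel_size_nm = sec$pixel_size_nm)
    rows[[length(rows) + 1]] <- data.frame(
      angle_to_tilt_axis_deg = ang,
      side_peak = pk$side, topbottom_peak = pk$topbottom,
      topbottom_over_side = pk$topbottom / pk$side)
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(outdir, "fig3h_wall_peaks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Side vs top/bottom wall peak intensities of a cross-section
#'
#' Quantifies the missing-wedge morphology: the peak density of the side
#' walls (along the lateral axis through the center) versus the top and
#' bottom walls (along the beam axis). Under a +/-60 degree wedge the
#' top/bottom walls fade and the ratio drops well below one.
#'
#' @param section a `cross_section`.
#' @param r_expected_nm expected ring radius locating the wall bands.
#' @return list with `side` and `topbottom` peak intensities.
#' @export
wall_peak_intensities <- function(section, r_expected_nm) {
  ctr <- section_center(section)
  nu <- nrow(section$data); nv <- ncol(section$data)
  vox <- section$pixel_size_nm
  lat <- (seq_len(nu) - ctr[1]) * vox
  beam <- (seq_len(nv) - ctr[2]) * vox
  band <- function(x) abs(abs(x) - r_expected_nm) <= max(1.5, vox)
  rows_c <- which(abs(beam) <= 1)
  cols_c <- which(abs(lat) <= 1)
  side <- max(section$data[band(lat), rows_c, drop = FALSE])
  topbottom <- max(section$data[cols_c, band(beam), drop = FALSE])
  list(side = side, topbottom = max(topbottom, 0))
}

run_stage_figs7 <- function(config, outdir) {
  candidates <- lapply(config$analysis$candidates_n_pf, function(n) {
    s <- spec_from_config(config); s$n_pf <- as.integer(n); s
  })
  protocol <- pf_protocol(voxel_size_nm = config$imaging$voxel_size_nm,
                          kernel_sigma_nm = config$imaging$kernel_sigma_nm,
                          wedge_half_angle_deg = config$recon$wedge_half_angle_deg,
                          tilt_step_deg = config$imaging$tilt_step_deg,
                          method = config$recon$method,
                          tube_length_nm = config$lattice$tube_length_nm)
  cls <- classify_protofilament_number(candidates, protocol,
                                       rotations_deg = config$analysis$rotations_deg)
  utils::write.table(cls$table, file.path(outdir, "figS7_asymmetry.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(summary = cls$summary, baseline = cls$baseline,
                            inferred_n_pf = cls$inferred_n_pf),
                       file.path(outdir, "figS7_classification.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cls
}

run_stage_fig5 <- function(config, outdir) {
  spec <- spec_from_config(config)
  im <- config$imaging
  geom <- tilt_geometry(im$tilt_min_deg, im$tilt_max_deg, im$tilt_step_deg)
  model <- orient_model(build_tube(spec), geom)
  map <- rasterize(model, im$voxel_size_nm, kernel_sigma_nm = im$kernel_sigma_nm)
  proj <- project_tilt_series(map, tilt_geometry(-1, 1, 1))$images[, , 2]
  spec_ps <- power_spectrum(proj, im$voxel_size_nm)
  pred <- predict_layer_line_pattern(spec, "outer")
  rep_est <- estimate_repeat(spec_ps, config$analysis$repeat_band_invnm)
  match <- match_spots(spec_ps, pred)
  utils::write.table(match$matches, file.path(outdir, "fig5_matches.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(repeat_nm = rep_est$repeat_nm,
                            uncertainty_nm = rep_est$uncertainty_nm,
                            layer_asymmetry = match$layer_asymmetry),
                       file.path(outdir, "fig5_repeat.json"),
                       auto_unbox = TRUE, digits = NA)
  list(matches = match, repeat_estimate = rep_est)
}

run_stage_figs8 <- function(config, outdir) {
  spec <- spec_from_config(config)
  im <- config$imaging
  model <- orient_model(build_tube(spec), tilt_geometry())
  wall <- 2 * (model$ring_radius_nm + spec$pf_diameter_nm) +
    6 * im$kernel_sigma_nm
  len <- diff(range(model$placements$y)) + 6 * im$kernel_sigma_nm + 2
  map <- rasterize(model, im$voxel_size_nm, box_nm = c(2 * wall, len, 2 * wall),
                   kernel_sigma_nm = im$kernel_sigma_nm)
  tomo <- wedge_tomogram(map, config$recon$wedge_half_angle_deg)
  prof <- asymmetry_profile_along_axis(tomo, window_nm = 12, step_nm = 10,
                                       r_expected_nm = model$ring_radius_nm)
  utils::write.table(prof$profile, file.path(outdir, "figS8_straightness.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  prof
}

#' Run a published-figure pipeline preset
#'
#' End-to-end drivers for the four simulation experiments: `"fig-3h"`
#' (missing-wedge morphology at 0/25/50/75 degrees to the tilt axis),
#' `"fig-s7"` (protofilament-number classification by rotation sweep),
#' `"fig-5"` (Fourier-Bessel layer-line analysis) and `"fig-s8"`
#' (straightness from the axial asymmetry profile). Writes TSV/JSON
#' outputs and a JSON run manifest (config snapshot, package version,
#' seed, per-file checksums) to the output directory; deterministic given
#' the seed.
#'
#' @param preset preset name, or `NULL` to use `config` as-is (runs all
#'   stages listed in `stages`).
#' @param config a [pipeline_config()]; preset overrides are applied on
#'   top.
#' @param output_dir output directory (created if needed).
#' @param stages which stage(s) to run when `preset` is `NULL`.
#' @return list with the stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(preset = NULL, config = pipeline_config(),
                         output_dir = config$output_dir,
                         stages = c("fig-3h", "fig-s7", "fig-5", "fig-s8")) {
  if (!is.null(preset)) {
    config <- pipeline_config(merge_config(preset_overrides(preset),
                                           list(output_dir = output_dir)))
    stages <- preset
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  results <- list()
  for (st in stages) {
    results[[st]] <- switch(st,
      "fig-3h" = run_stage_fig3h(config, output_dir),
      "fig-s7" = run_stage_figs7(config, output_dir),
      "fig-5" = run_stage_fig5(config, output_dir),
      "fig-s8" = run_stage_figs8(config, output_dir),
      stop(sprintf("pipeline stage '%s' failed to start: unknown stage", st)))
  }
  files <- list.files(output_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(package_version = as.character(utils::packageVersion("bmtsim")),
                   seed = config$seed,
                   stages = stages,
                   config = unclass(write_safe_config(config)),
                   files = data.frame(path = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}

## Inf is not JSON-representable; stringify non-finite leaves.
write_safe_config <- function(config) {
  rapply(unclass(config), function(x) {
    if (is.numeric(x) && any(!is.finite(x))) as.character(x) else x
  }, how = "replace")
}
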