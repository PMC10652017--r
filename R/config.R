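# Configuration files (YAML), validation, and the end-to-end pipeline.

config_schema <- list(
  top = c("seed", "output_dir", "scenario", "noise_sigma", "spectrometer",
          "sequence", "species", "phantom", "weighting", "recon", "quantify"),
  spectrometer = c("field_strength", "deuterium_frequency", "proton_frequency", "carrier_offset"),
  sequence = c("mode", "TR", "flip_angle", "matrix_size", "fov", "slice_thickness", "me", "csi"),
  me = c("n_echoes", "echo_spacing", "first_echo_time", "flyback_duration", "readout_bandwidth"),
  csi = c("n_fid_points", "dwell_time", "n_discard"),
  species = c("label", "chemical_shift", "T1", "T2", "enrichment_factor"),
  phantom = c("grid_shape", "fov", "tube_concentration", "b0_inhomogeneity", "times"),
  weighting = c("na", "base_reps"),
  recon = c("recon_size", "psi_tolerance", "max_iterations", "kinetic_lambda", "mask_threshold"),
  quantify = c("reference_value", "detection_snr", "detection_window")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop_param("unknown configuration key%s at %s: %s",
               if (length(bad) > 1) "s" else "", where, paste(bad, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing spectrometer, sequence, species,
#' phantom, weighting, reconstruction and quantification parameters, checks
#' it (unknown keys are rejected with their location, missing sections are
#' listed), and materializes the validated spec objects. The shipped
#' default, `system.file("extdata", "default_config.yaml", package =
#' "deutrecon")`, carries the study's acquisition defaults.
#'
#' @param path path to a YAML file.
#' @return A `run_config`: validated `spectrometer`, `sequence`, `species`,
#'   plus the raw parameter list (`raw`) used for round-tripping.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param("configuration file not found: %s", path)
  raw <- yaml::read_yaml(path)
  required <- c("scenario", "spectrometer", "sequence", "species", "phantom",
                "weighting", "recon", "quantify")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_param("configuration %s is missing required section%s: %s",
               path, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", "))
  check_keys(raw, config_schema$top, "top level")
  check_keys(raw$spectrometer, config_schema$spectrometer, "spectrometer")
  check_keys(raw$sequence, config_schema$sequence, "sequence")
  if (!is.null(raw$sequence$me)) check_keys(raw$sequence$me, config_schema$me, "sequence$me")
  if (!is.null(raw$sequence$csi)) check_keys(raw$sequence$csi, config_schema$csi, "sequence$csi")
  for (i in seq_along(raw$species))
    check_keys(raw$species[[i]], config_schema$species, sprintf("species[%d]", i))
  check_keys(raw$phantom, config_schema$phantom, "phantom")
  check_keys(raw$weighting, config_schema$weighting, "weighting")
  check_keys(raw$recon, config_schema$recon, "recon")
  check_keys(raw$quantify, config_schema$quantify, "quantify")
  if (!raw$scenario %in% c("tubes", "tumor", "pancreatitis", "control"))
    stop_param("scenario must be one of tubes/tumor/pancreatitis/control")

  spect <- do.call(spectrometer_spec, raw$spectrometer)
  seq_args <- raw$sequence
  for (k in c("matrix_size", "fov")) if (!is.null(seq_args[[k]])) seq_args[[k]] <- unlist(seq_args[[k]])
  seqd <- do.call(sequence_spec, seq_args)
  species <- lapply(raw$species, function(s) do.call(species_spec, s))
  names(species) <- vapply(species, `[[`, character(1), "label")

  structure(list(scenario = raw$scenario, seed = raw$seed %||% 1L,
                 output_dir = raw$output_dir %||% "deutrecon_out",
                 noise_sigma = raw$noise_sigma %||% 0,
                 spectrometer = spect, sequence = seqd, species = species,
                 phantom = raw$phantom, weighting = raw$weighting,
                 recon = raw$recon, quantify = raw$quantify, raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> scenario '%s', %s, seed %s, noise %g\n",
              x$scenario, x$sequence$mode, format(x$seed), x$noise_sigma))
  invisible(x)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config$raw, f)
  unname(tools::md5sum(f))
}

#' Run the full phantom-to-quantification pipeline
#'
#' Chains phantom generation, k-space simulation, frame reconstruction,
#' IDEAL (or kinetic-regularized) species separation and concentration
#' calibration according to a [load_config()] configuration, writing maps
#' to NIfTI, time courses and SNR tables to CSV, and a JSON manifest (file
#' list, metrics, configuration hash, seed). Deterministic given the seed.
#'
#' @param config a `run_config`.
#' @param out_dir output directory; defaults to the configuration's.
#' @return The manifest, invisibly also written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  ph_cfg <- config$phantom
  grid <- as.integer(unlist(ph_cfg$grid_shape %||% c(64L, 64L)))
  seqd <- config$sequence
  n_dims <- if (seqd$mode == "ME_SSFP") 1L else 2L
  wt <- build_weight_table(seqd$matrix_size[2], na = config$weighting$na %||% 1,
                           base_reps = config$weighting$base_reps %||% 1,
                           n_dims = n_dims)
  rc <- config$recon
  qc <- config$quantify
  files <- character(); metrics <- list()
  write_tc <- function(tc, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(tc), f, row.names = FALSE)
    f
  }

  if (config$scenario == "tubes") {
    phantom <- make_tube_phantom(grid_shape = grid, fov = seqd$fov,
                                 tube_concentration = ph_cfg$tube_concentration %||% 50,
                                 b0_inhomogeneity = ph_cfg$b0_inhomogeneity %||% 30,
                                 seed = seed)
    files <- c(files, write_phantom_nifti(phantom, out_dir, "phantom"))
    ks <- simulate_kspace(phantom, seqd, wt, config$spectrometer, config$species,
                          noise_sigma = config$noise_sigma, seed = seed)
    files <- c(files, write_kspace(ks, file.path(out_dir, "kspace.rds")))
    fr <- reconstruct_frames(ks, recon_size = rc$recon_size %||% 64)
    psi0 <- resample_map(phantom$b0_map, rc$recon_size %||% 64)
    noise <- resample_mask(phantom$roi_masks$noise_region, rc$recon_size %||% 64)
    # the noise region is fitted too so that species-map SNR can be measured
    fit <- ideal_fit(fr, psi_init = psi0,
                     psi_tolerance = rc$psi_tolerance %||% 0.01,
                     max_iterations = rc$max_iterations %||% 50,
                     mask = default_fit_mask(fr, rc$mask_threshold %||% 0.05) | noise)
    files <- c(files, write_species_maps(fit, out_dir))
    ref <- resample_mask(phantom$roi_masks$reference_region, rc$recon_size %||% 64)
    conc <- calibrate_concentration(fit, ref, seqd,
                                    reference_value = qc$reference_value %||% 10)
    snr <- vapply(names(phantom$roi_masks)[1:3], function(rn) {
      roi <- resample_mask(phantom$roi_masks[[rn]], rc$recon_size %||% 64)
      sp <- sub("tube_", "", rn)
      measure_snr(abs(fit$rho[, , match(sp, fit$species)]), roi, noise)
    }, numeric(1))
    snr_df <- data.frame(roi = names(snr), snr = as.numeric(snr))
    files <- c(files, write_tc(snr_df, "snr_report.csv"))
    conc_c <- calibrate_concentration(fit, ref, seqd,
                                      reference_value = qc$reference_value %||% 10,
                                      magnitude = FALSE)
    tube_mean <- vapply(c("HDO", "glucose", "lactate"),
                        function(sp) recover_tube_concentration(conc_c, phantom, sp),
                        numeric(1))
    metrics <- list(tube_mean_mM = as.list(tube_mean), snr = as.list(snr),
                    scan_minutes = scan_duration(wt, seqd) / 60)
  } else {
    times <- unlist(ph_cfg$times %||% seq(0, 90, by = 15))
    series <- make_abdominal_phantom(config$scenario, times = times,
                                     grid_shape = grid, fov = seqd$fov,
                                     b0_inhomogeneity = ph_cfg$b0_inhomogeneity %||% 30,
                                     seed = seed)
    rsz <- rc$recon_size %||% 64
    frames <- lapply(seq_along(times), function(i)
      reconstruct_frames(simulate_kspace(series$frames[[i]], seqd, wt,
                                         config$spectrometer, config$species,
                                         noise_sigma = config$noise_sigma,
                                         seed = seed * 1000L + i),
                         recon_size = rsz))
    psi0 <- resample_map(series$frames[[1]]$b0_map, rsz)
    lam <- rc$kinetic_lambda %||% 1
    body <- resample_mask(series$roi_masks$body, rsz)
    noise_mask <- resample_mask(series$roi_masks$noise_region, rsz)
    rk <- rk_specrecon(frames, psi_init = psi0, lambda = lam,
                       psi_tolerance = rc$psi_tolerance %||% 0.01,
                       max_iterations = rc$max_iterations %||% 50,
                       mask = body | noise_mask)
    ref <- resample_mask(series$roi_masks$reference_region, rsz)
    conc_series <- lapply(rk$fits, function(f)
      calibrate_concentration(f, ref, seqd,
                              reference_value = qc$reference_value %||% 10,
                              pre_injection_reference =
                                rk$fits[[1]]$rho[, , match("HDO", rk$fits[[1]]$species)]))
    tumor <- resample_mask(series$roi_masks$tumor, rsz)
    tc <- roi_timecourse(conc_series, tumor, times)
    files <- c(files, write_tc(tc, "tumor_timecourse.csv"))
    lac <- tc[tc$species == "lactate", ]
    # coherent lactate ROI means vs a matched lactate-free tissue null
    null_roi <- body & !tumor & !resample_mask(series$roi_masks$kidney, rsz) &
      !resample_mask(series$roi_masks$bladder, rsz)
    lac_maps <- lapply(rk$fits, function(f) f$rho[, , match("lactate", f$species)])
    det <- roi_detection(lac_maps, tumor, null_roi, seqd$fov)
    window <- unlist(qc$detection_window %||% c(40, 70))
    in_win <- times >= window[1] & times <= window[2]
    det_win <- if (any(in_win)) max(det$det[in_win]) else max(det$det)
    # peak time from the coherent complex ROI mean (robust to the Rician floor)
    lac_coh <- vapply(lac_maps, function(m) Mod(mean(m[tumor])), numeric(1))
    files <- c(files, write_species_maps(rk$fits[[which.max(lac_coh)]], out_dir, "species_peak"))
    metrics <- list(lactate_peak_mM = max(lac$mean_mM),
                    lactate_peak_time_min = times[which.max(lac_coh)],
                    lactate_detected = det_win >= (qc$detection_snr %||% 3),
                    peak_detection_snr = det_win,
                    scan_minutes = scan_duration(wt, seqd) / 60)
  }
  manifest <- list(package = "deutrecon", scenario = config$scenario,
                   seed = seed, config_hash = config_hash(config),
                   files = basename(files), metrics = metrics)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Nearest-neighbour map/mask resampling from the phantom truth grid to the
# reconstruction grid (both square, same FOV).
resample_map <- function(map, size) {
  n <- nrow(map)
  if (n == size) return(map)
  idx <- pmin(pmax(round((seq_len(size) - 1 - size %/% 2) * n / size) + n %/% 2 + 1L, 1L), n)
  map[idx, idx]
}

resample_mask <- function(mask, size) {
  resample_map(mask * 1, size) > 0.5
}
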