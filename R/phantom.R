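# Digital ground-truth phantoms: a three-tube validation phantom and
# abdominal kinetic phantoms (tumor / pancreatitis / control scenarios).
# Concentrations are in mM of 2H equivalents on a square grid; the B0 map is
# in Hz in the deuterium frame.

new_dmi_phantom <- function(grid_shape, fov, species_maps, b0_map, roi_masks, meta = list()) {
  shp <- dim(species_maps[[1]])
  for (m in species_maps)
    if (any(dim(m) != shp) || any(m < -1e-12)) stop_param("species maps must share one shape and be nonnegative")
  if (any(dim(b0_map) != shp)) stop_param("b0_map shape mismatch")
  structure(list(grid_shape = as.integer(grid_shape), fov = fov,
                 species_maps = species_maps, b0_map = b0_map,
                 roi_masks = roi_masks, meta = meta),
            class = "dmi_phantom")
}

#' @export
print.dmi_phantom <- function(x, ...) {
  cat(sprintf("<dmi_phantom> %dx%d grid, FOV %gx%g mm\n",
              x$grid_shape[1], x$grid_shape[2], x$fov[1], x$fov[2]))
  for (s in names(x$species_maps))
    cat(sprintf("  %-8s max %.2f mM\n", s, max(x$species_maps[[s]])))
  cat("  ROIs:", paste(names(x$roi_masks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dmi_phantom <- function(x, species = names(x$species_maps), ...) {
  op <- graphics::par(mfrow = c(1, length(species)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (s in species) {
    graphics::image(x$species_maps[[s]], axes = FALSE, main = s,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}

# Smooth second-order polynomial field map with seeded coefficients, scaled
# to the requested peak amplitude (Hz, deuterium frame).
make_b0_map <- function(grid_shape, amplitude, seed = NULL) {
  n1 <- grid_shape[1]; n2 <- grid_shape[2]
  u <- (seq_len(n1) - 1 - n1 %/% 2) / (n1 / 2)
  v <- (seq_len(n2) - 1 - n2 %/% 2) / (n2 / 2)
  U <- matrix(u, n1, n2); V <- matrix(v, n1, n2, byrow = TRUE)
  cf <- with_seed(seed, stats::rnorm(5))
  b0 <- cf[1] * U + cf[2] * V + cf[3] * U^2 + cf[4] * V^2 + cf[5] * U * V
  if (amplitude == 0 || max(abs(b0)) == 0) return(b0 * 0)
  b0 * (amplitude / max(abs(b0)))
}

#' Three-tube validation phantom
#'
#' Three 5 mm tubes containing enriched HDO, glucose and lactate at a common
#' concentration (~50 mM), immersed in a water bath carrying the 10 mM
#' natural-abundance HDO background. ROI masks are provided for each tube,
#' for a bath reference region used by the concentration calibration, and
#' for a pure-noise region outside the bath.
#'
#' @param grid_shape length-2 integer grid (default 64 x 64 truth grid).
#' @param fov field of view in mm (length 2).
#' @param tube_concentration tube 2H concentration in mM (default 50).
#' @param b0_inhomogeneity peak amplitude of the smooth polynomial B0 map in
#'   Hz (deuterium frame).
#' @param seed RNG seed controlling the B0 polynomial coefficients.
#' @param tube_diameter tube inner diameter in mm.
#' @param natural_abundance bath HDO concentration in mM.
#' @return A `dmi_phantom`.
#' @examples
#' ph <- make_tube_phantom(seed = 1)
#' sapply(ph$species_maps, max)
#' @export
make_tube_phantom <- function(grid_shape = c(64L, 64L), fov = c(40, 40),
                              tube_concentration = 50, b0_inhomogeneity = 30,
                              seed = NULL, tube_diameter = 5,
                              natural_abundance = 10) {
  if (tube_concentration < 0) stop_param("tube_concentration must be nonnegative")
  r_tube <- tube_diameter / 2
  ring <- 8                                 # tube centers on an 8 mm ring
  bath_r <- 15
  if (2 * ring * sin(pi / 3) <= tube_diameter)
    stop_param("tubes of diameter %g mm would overlap on the %g mm ring", tube_diameter, ring)
  if (ring + r_tube >= min(fov) / 2)
    stop_param("FOV %g mm too small for the tube layout", min(fov))
  ang <- c(90, 210, 330) * pi / 180
  centers <- lapply(ang, function(a) ring * c(cos(a), sin(a)))
  cov <- lapply(centers, function(ct) disk_coverage(grid_shape, fov, ct, r_tube))
  bath <- disk_coverage(grid_shape, fov, c(0, 0), bath_r)

  hdo <- natural_abundance * bath + (tube_concentration - natural_abundance) * cov[[1]]
  glc <- tube_concentration * cov[[2]]
  lac <- tube_concentration * cov[[3]]
  if (tube_concentration == 0) hdo <- hdo * 0   # empty-tube case: no bath signal either

  px <- fov[1] / grid_shape[1]
  x <- (seq_len(grid_shape[1]) - 1 - grid_shape[1] %/% 2) * px
  y <- (seq_len(grid_shape[2]) - 1 - grid_shape[2] %/% 2) * (fov[2] / grid_shape[2])
  r <- sqrt(outer(x^2, y^2, "+"))
  masks <- list(
    tube_HDO = cov[[1]] > 0.5,
    tube_glucose = cov[[2]] > 0.5,
    tube_lactate = cov[[3]] > 0.5,
    bath = bath > 0.5,
    reference_region = r <= 4,
    noise_region = r >= bath_r + 3
  )
  new_dmi_phantom(grid_shape, fov,
                  species_maps = list(HDO = hdo, glucose = glc, lactate = lac),
                  b0_map = make_b0_map(grid_shape, b0_inhomogeneity, seed),
                  roi_masks = masks,
                  meta = list(kind = "tubes", tube_concentration = tube_concentration,
                              tube_centers = centers, tube_radius = r_tube, seed = seed))
}

#' Gamma-variate kinetic curve parameters
#'
#' Each (ROI, species) pair follows `baseline + amplitude * g(t)` with the
#' unit-peak gamma variate
#' `g(t) = ((t-onset)/ttp)^(ttp/decay) * exp((ttp - (t-onset))/decay)` for
#' `t > onset` and 0 before, peaking at `onset + ttp`.
#'
#' @param amplitude peak excursion above baseline, mM (>= 0).
#' @param onset delay before uptake starts, minutes.
#' @param time_to_peak time from onset to peak, minutes (> 0).
#' @param decay exponential decay constant, minutes (> 0).
#' @param baseline constant background, mM (>= 0).
#' @return A `kinetic_entry` list.
#' @export
kinetic_entry <- function(amplitude, onset = 0, time_to_peak, decay, baseline = 0) {
  if (amplitude < 0 || baseline < 0) stop_param("amplitude and baseline must be nonnegative")
  if (time_to_peak <= 0 || decay <= 0) stop_param("time_to_peak and decay must be positive")
  if (onset < 0) stop_param("onset must be nonnegative")
  structure(list(amplitude = amplitude, onset = onset, time_to_peak = time_to_peak,
                 decay = decay, baseline = baseline), class = "kinetic_entry")
}

#' Kinetic model for an abdominal scenario
#'
#' A named collection of [kinetic_entry()] curves keyed `"roi.species"`
#' (e.g. `"tumor.lactate"`). ROI curves add to the whole-body curve of the
#' same species inside their mask.
#'
#' @param entries named list of [kinetic_entry()] objects.
#' @return Object of class `kinetic_model`.
#' @seealso [default_kinetics()]
#' @export
kinetic_model <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  for (e in entries) stopifnot(inherits(e, "kinetic_entry"))
  structure(entries, class = "kinetic_model")
}

#' Default kinetic models for the abdominal scenarios
#'
#' Qualitative defaults emulating reported deuterated-glucose kinetics:
#' early renal glucose uptake followed by bladder accumulation, a gradual
#' body-wide HDO rise on top of the 10 mM natural-abundance baseline, and --
#' in the tumor scenario only -- lactate formation in the tumor peaking
#' about 50 min after injection at a sub-glucose amplitude. Pancreatitis and
#' control differ from the tumor scenario by having no lactate production
#' anywhere (pancreatitis additionally shows a mildly elevated body glucose
#' curve, emulating inflammation-driven uptake without glycolytic lactate).
#'
#' @param scenario `"tumor"`, `"pancreatitis"` or `"control"`.
#' @return A [kinetic_model()].
#' @export
default_kinetics <- function(scenario = c("tumor", "pancreatitis", "control")) {
  scenario <- match.arg(scenario)
  e <- list(
    body.HDO        = kinetic_entry(4, onset = 0, time_to_peak = 90, decay = 90, baseline = 10),
    body.glucose    = kinetic_entry(6, onset = 0, time_to_peak = 10, decay = 25),
    kidney.glucose  = kinetic_entry(12, onset = 1, time_to_peak = 8, decay = 30),
    bladder.glucose = kinetic_entry(14, onset = 5, time_to_peak = 35, decay = 80)
  )
  if (scenario == "tumor") {
    e$tumor.glucose <- kinetic_entry(6, onset = 3, time_to_peak = 25, decay = 50)
    e$tumor.lactate <- kinetic_entry(1.5, onset = 10, time_to_peak = 40, decay = 40)
  }
  if (scenario == "pancreatitis")
    e$body.glucose <- kinetic_entry(7, onset = 0, time_to_peak = 12, decay = 28)
  kinetic_model(e)
}

#' Evaluate a kinetic curve
#'
#' @param model a [kinetic_model()].
#' @param roi,species the `"roi.species"` key to evaluate; an absent key is
#'   a flat zero curve.
#' @param t times in minutes (nonnegative).
#' @return Concentrations in mM, same length as `t`.
#' @export
evaluate_kinetic <- function(model, roi, species, t) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(t < 0)) stop_param("t must be nonnegative (minutes)")
  e <- model[[paste(roi, species, sep = ".")]]
  if (is.null(e)) return(rep(0, length(t)))
  tau <- t - e$onset
  k <- e$time_to_peak / e$decay
  g <- ifelse(tau > 0,
              (pmax(tau, 0) / e$time_to_peak)^k * exp((e$time_to_peak - tau) / e$decay),
              0)
  e$baseline + e$amplitude * g
}

abdominal_geometry <- function(grid_shape, fov) {
  list(
    body    = list(kind = "ellipse", center = c(0, 0), semi = c(17, 13)),
    kidney  = list(kind = "disk", center = c(-8, 5), r = 3.5),
    bladder = list(kind = "disk", center = c(8, -6), r = 3),
    tumor   = list(kind = "disk", center = c(-6, -6), r = 5),
    reference_region = list(kind = "disk", center = c(8, 6), r = 4)
  )
}

#' Abdominal kinetic phantom series
#'
#' Builds a time series of single-slice abdominal phantoms with body,
#' kidney, bladder and tumor compartments whose HDO/glucose/lactate
#' concentrations follow the scenario's [kinetic_model()]. Lactate is
#' produced only in the tumor compartment of the `"tumor"` scenario; the
#' pancreatitis and control scenarios stay at zero lactate throughout. The
#' tumor ROI mask exists in every scenario (as normal tissue) so that the
#' same ROI protocol can be applied across scenarios.
#'
#' @param scenario `"tumor"`, `"pancreatitis"` or `"control"`.
#' @param kinetics a [kinetic_model()]; defaults to [default_kinetics()].
#' @param times acquisition times in minutes, strictly increasing.
#' @param grid_shape,fov truth grid and field of view (mm).
#' @param b0_inhomogeneity peak B0 amplitude in Hz.
#' @param seed RNG seed for the B0 polynomial.
#' @return A `dmi_phantom_series`: list with `times`, `frames` (one
#'   `dmi_phantom` per time), shared `roi_masks`, `scenario`, `kinetics`.
#' @export
make_abdominal_phantom <- function(scenario = c("tumor", "pancreatitis", "control"),
                                   kinetics = NULL, times = seq(0, 90, by = 15),
                                   grid_shape = c(64L, 64L), fov = c(40, 40),
                                   b0_inhomogeneity = 30, seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(kinetics)) kinetics <- default_kinetics(scenario)
  stopifnot(inherits(kinetics, "kinetic_model"))
  if (length(times) < 1L || any(diff(times) <= 0) || any(times < 0))
    stop_param("times must be nonnegative and strictly increasing (minutes)")
  if (scenario != "tumor" && any(grepl("\\.lactate$", names(kinetics))))
    stop_param("lactate kinetics are only admissible in the tumor scenario")

  geo <- abdominal_geometry(grid_shape, fov)
  cov <- list(
    body = {
      b <- ellipse_mask(grid_shape, fov, geo$body$center, geo$body$semi)
      b * 1
    },
    kidney  = disk_coverage(grid_shape, fov, geo$kidney$center, geo$kidney$r),
    bladder = disk_coverage(grid_shape, fov, geo$bladder$center, geo$bladder$r),
    tumor   = disk_coverage(grid_shape, fov, geo$tumor$center, geo$tumor$r)
  )
  body_out <- !ellipse_mask(grid_shape, fov, geo$body$center, geo$body$semi + 3)
  masks <- list(
    body = cov$body > 0.5,
    kidney = cov$kidney > 0.5,
    bladder = cov$bladder > 0.5,
    tumor = cov$tumor > 0.5,
    reference_region = disk_coverage(grid_shape, fov, geo$reference_region$center,
                                     geo$reference_region$r) > 0.5,
    noise_region = body_out
  )
  b0 <- make_b0_map(grid_shape, b0_inhomogeneity, seed)
  species <- c("HDO", "glucose", "lactate")
  rois <- c("body", "kidney", "bladder", "tumor")
  frames <- lapply(times, function(t) {
    maps <- lapply(species, function(sp) {
      m <- matrix(0, grid_shape[1], grid_shape[2])
      for (roi in rois) {
        c_t <- evaluate_kinetic(kinetics, roi, sp, t)
        if (c_t != 0) m <- m + c_t * cov[[roi]]
      }
      m
    })
    names(maps) <- species
    new_dmi_phantom(grid_shape, fov, maps, b0, masks,
                    meta = list(kind = "abdominal", scenario = scenario, time = t, seed = seed))
  })
  structure(list(times = times, frames = frames, roi_masks = masks,
                 scenario = scenario, kinetics = kinetics,
                 grid_shape = as.integer(grid_shape), fov = fov, seed = seed),
            class = "dmi_phantom_series")
}

#' @export
print.dmi_phantom_series <- function(x, ...) {
  cat(sprintf("<dmi_phantom_series> scenario '%s', %d time points (%g-%g min), %dx%d grid\n",
              x$scenario, length(x$times), min(x$times), max(x$times),
              x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Write phantom maps to NIfTI
#'
#' One single-slice NIfTI per species (static phantom) or a 4D stack over
#' the kinetic series.
#'
#' @param phantom a `dmi_phantom` or `dmi_phantom_series`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- function(ph) c(ph$fov[1] / ph$grid_shape[1], ph$fov[2] / ph$grid_shape[2], 1)
  files <- character()
  if (inherits(phantom, "dmi_phantom")) {
    for (s in names(phantom$species_maps)) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, s))
      RNifti::writeNifti(array(phantom$species_maps[[s]], c(phantom$grid_shape, 1L)), f)
      files <- c(files, f)
    }
    f <- file.path(dir, sprintf("%s_b0.nii.gz", prefix))
    RNifti::writeNifti(array(phantom$b0_map, c(phantom$grid_shape, 1L)), f)
    files <- c(files, f)
  } else if (inherits(phantom, "dmi_phantom_series")) {
    shp <- phantom$grid_shape
    for (s in names(phantom$frames[[1]]$species_maps)) {
      arr <- array(0, c(shp, 1L, length(phantom$times)))
      for (i in seq_along(phantom$frames))
        arr[, , 1L, i] <- phantom$frames[[i]]$species_maps[[s]]
      f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, s))
      RNifti::writeNifti(arr, f)
      files <- c(files, f)
    }
  } else stop_param("phantom must be a dmi_phantom or dmi_phantom_series")
  invisible(files)
}
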