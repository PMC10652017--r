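# Forward simulation of ME-SSFP / CSI-SSFP k-space series with uniform or
# Hanning-weighted signal averaging and calibrated complex noise.
#
# Bookkeeping conventions (used everywhere):
#  * k-space arrays are stored centered: DC at 0-based index N/2.
#  * ME-SSFP: axis 1 is the readout (frequency-encode) direction, axis 2 the
#    phase-encode direction; one acquisition = one TR = a full readout row at
#    every echo time, so weights are a 1D table over the PE axis.
#  * CSI-SSFP: both axes are phase encoded; one acquisition = one TR = the
#    retained FID for a single (k1, k2) pair; weights are a 2D table.
#  * Weighted lines are SUMMED, not averaged: the window is imposed
#    physically as an apodization; reconstruction divides by the single
#    global factor total_acquisitions / n_pe.

#' Acquisition weighting table
#'
#' Number of signal averages to invest per phase-encode index, following a
#' raised-cosine (Hanning-like) window with maximum at the k-space center:
#' `w(k) = max(1, round(base_reps * na * H(k)))`, where `H` has peak 1 at DC
#' and the 2D window is the separable outer product. `na = 1` is the uniform
#' scheme (`H == 1`, all weights `base_reps`). With `quantize = FALSE` the
#' ideal continuous schedule `base_reps * na * H(k)` is returned (weights
#' may then be non-integer and reach 0 at the edges); `na = 2` (1D) and
#' `na = 4` (2D) make the continuous schedule budget-matched to the uniform
#' scheme with the same `base_reps`, since the window sums to exactly
#' N/2 per axis.
#'
#' @param n_pe phase-encode points per axis (>= 2).
#' @param na weighting coefficient (>= 1); 1 means uniform.
#' @param base_reps repetitions of the baseline scheme (>= 1).
#' @param n_dims 1 (ME-SSFP) or 2 (CSI-SSFP).
#' @param quantize round to integer averages with a floor of 1 (default).
#' @return A `weight_table`: weights vector (1D) or matrix (2D) plus
#'   metadata (`na`, `base_reps`, `n_dims`, `total_budget`).
#' @examples
#' w <- build_weight_table(32, na = 4, base_reps = 512, n_dims = 1)
#' max(w$weights); sum(w$weights)
#' @export
build_weight_table <- function(n_pe, na = 1, base_reps = 1, n_dims = 1,
                               quantize = TRUE) {
  if (!is_scalar_num(n_pe) || n_pe < 2) stop_param("n_pe must be >= 2")
  if (!is_scalar_num(na) || na < 1) stop_param("na must be >= 1")
  if (!is_scalar_num(base_reps) || base_reps < 1) stop_param("base_reps must be >= 1")
  if (!n_dims %in% c(1, 2)) stop_param("n_dims must be 1 or 2")
  n_pe <- as.integer(n_pe)
  H <- if (na == 1) rep(1, n_pe) else hanning_window(n_pe)
  w <- if (n_dims == 1) base_reps * na * H else base_reps * na * outer(H, H)
  if (quantize) w <- pmax(round(w), 1)
  structure(list(weights = w, na = na, base_reps = base_reps, n_dims = n_dims,
                 n_pe = n_pe, quantized = quantize, total_budget = sum(w)),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %dD, n_pe %d, NA %g, base %g, %s; total %g averages (center %g)\n",
              x$n_dims, x$n_pe, x$na, x$base_reps,
              if (x$quantized) "quantized" else "continuous",
              x$total_budget, max(x$weights)))
  invisible(x)
}

#' Spectral sample times
#'
#' Times (seconds) at which each spectral point of the truncated FID is
#' sampled, relative to the excitation. ME-SSFP: `first_echo_time + k *
#' echo_spacing` for the `n_echoes` gradient echoes. CSI-SSFP: the FID
#' points that survive the digital-filter discard,
#' `(n_discard ... n_fid_points-1) * dwell_time`.
#'
#' @param seq a [sequence_spec()].
#' @return Numeric vector of times in seconds.
#' @examples
#' length(sample_times(csi_sequence()))  # 42 retained FID points
#' @export
sample_times <- function(seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  if (seq$mode == "ME_SSFP") {
    (seq$me$first_echo_time + (seq_len(seq$me$n_echoes) - 1) * seq$me$echo_spacing) / 1000
  } else {
    (seq$csi$n_discard:(seq$csi$n_fid_points - 1)) * seq$csi$dwell_time / 1000
  }
}

#' Flyback dead-time fraction
#'
#' Fraction of the TR spent in the flyback (rewinding) gradients of an
#' ME-SSFP readout train, during which no data are collected; this is the
#' sampling-efficiency concession relative to a gradient-free FID readout.
#'
#' @param seq an ME-SSFP [sequence_spec()].
#' @return `n_echoes * flyback_duration / TR`.
#' @export
flyback_duty_cycle <- function(seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  if (seq$mode != "ME_SSFP") stop_param("flyback_duty_cycle applies to ME_SSFP sequences only")
  seq$me$n_echoes * seq$me$flyback_duration / seq$TR
}

#' Total scan duration of a weighting schedule
#'
#' Every average is one TR: ME-SSFP spends `sum(weights)` TRs (each
#' acquisition covers a full readout row), CSI-SSFP spends one TR per
#' average of each phase-encode pair.
#'
#' @param weights a [build_weight_table()] result.
#' @param seq a [sequence_spec()].
#' @return Duration in seconds.
#' @examples
#' scan_duration(build_weight_table(32, 1, 32, n_dims = 2), csi_sequence()) / 60
#' @export
scan_duration <- function(weights, seq) {
  stopifnot(inherits(weights, "weight_table"), inherits(seq, "sequence_spec"))
  sum(weights$weights) * seq$TR / 1000
}

# Per-sample complex-noise std of one acquisition: noise_sigma is referred
# to a 1 kHz bandwidth, so sigma_pt = noise_sigma * sqrt(BW / 1 kHz). ME and
# CSI comparisons at one noise_sigma are thus matched in noise spectral
# density (ME: receiver bandwidth; CSI: 1 / dwell).
acquisition_bandwidth <- function(seq) {
  if (seq$mode == "ME_SSFP") seq$me$readout_bandwidth else 1000 / seq$csi$dwell_time
}

#' Simulate a k-space series
#'
#' Forward model of both spectroscopic-imaging modes. For each spectral
#' sample time `t_n` the complex transverse image
#' \deqn{I_n(x) = \sum_m A_m C_m(x) \exp(2 i \pi (f_m + \psi(x)) t_n)}
#' (with `A_m` the steady-state amplitude from [ssfp_attenuation()], `C_m`
#' the phantom concentration map and `psi` the B0 map) is sampled on the
#' acquisition matrix as the central block of its discrete Fourier
#' transform. Each phase-encode line is the sum of `w(k)` independent
#' acquisitions, each carrying i.i.d. circular complex Gaussian noise whose
#' per-sample std scales with the square root of the acquisition bandwidth
#' (see `noise_sigma`). Identical seeds give bit-identical output.
#'
#' @param phantom a `dmi_phantom` whose grid is at least the acquisition
#'   matrix.
#' @param seq a [sequence_spec()].
#' @param weights a [build_weight_table()] matching the sequence mode (1D
#'   for ME, 2D for CSI).
#' @param spectrometer a [spectrometer_spec()].
#' @param species list of [species_spec()] whose labels match the phantom's
#'   species maps.
#' @param noise_sigma complex-component noise std per acquisition per sample
#'   at a 1 kHz reference bandwidth (0 = noiseless).
#' @param seed RNG seed (restored on exit).
#' @return A `kspace_series`: complex `samples` array (k1, k2, spectral),
#'   `sample_times`, `weights`, `noise_sigma`, `seed`, `sequence`,
#'   `species`, `spectrometer`, and the global `normalization` to be applied
#'   at reconstruction.
#' @export
simulate_kspace <- function(phantom, seq, weights, spectrometer, species,
                            noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(phantom, "dmi_phantom"), inherits(seq, "sequence_spec"),
            inherits(weights, "weight_table"), inherits(spectrometer, "spectrometer_spec"))
  n1 <- seq$matrix_size[1]; n2 <- seq$matrix_size[2]
  if (any(phantom$grid_shape < seq$matrix_size))
    stop_param("acquisition matrix %dx%d exceeds phantom grid %dx%d",
               n1, n2, phantom$grid_shape[1], phantom$grid_shape[2])
  labels <- vapply(species, function(s) s$label, character(1))
  if (!all(labels %in% names(phantom$species_maps)))
    stop_param("phantom lacks species maps for: %s",
               paste(setdiff(labels, names(phantom$species_maps)), collapse = ", "))
  shifts <- vapply(species, function(s) ppm_to_hz(s$chemical_shift, spectrometer), numeric(1))
  if (anyDuplicated(round(shifts, 9))) stop_param("species chemical shifts must be distinct")
  if ((seq$mode == "ME_SSFP") != (weights$n_dims == 1))
    stop_param("weight table dimensionality (%dD) does not match sequence mode %s",
               weights$n_dims, seq$mode)
  if (weights$n_pe != n2) stop_param("weight table n_pe (%d) != matrix PE size (%d)", weights$n_pe, n2)

  amps <- vapply(species, function(s) ssfp_attenuation(s, seq), numeric(1))
  times <- sample_times(seq)
  psi <- phantom$b0_map
  wmat <- if (weights$n_dims == 1) {
    matrix(weights$weights, n1, n2, byrow = TRUE)
  } else weights$weights
  sigma_pt <- noise_sigma * sqrt(acquisition_bandwidth(seq) / 1000)

  samples <- array(complex(real = 0), c(n1, n2, length(times)))
  base_phase <- 2i * pi * psi
  signal_maps <- Map(function(lbl, A) A * phantom$species_maps[[lbl]], labels, amps)
  with_seed(seed, {
    for (n in seq_along(times)) {
      tn <- times[n]
      img <- matrix(complex(real = 0), phantom$grid_shape[1], phantom$grid_shape[2])
      for (m in seq_along(species))
        img <- img + signal_maps[[m]] * exp(2i * pi * shifts[m] * tn)
      img <- img * exp(base_phase * tn)
      k_full <- fft2_centered(img)
      s <- center_block(k_full, n1, n2)
      page <- wmat * s
      if (sigma_pt > 0) {
        sd_k <- sigma_pt * sqrt(wmat)
        page <- page + complex(real = stats::rnorm(n1 * n2, 0, sd_k),
                               imaginary = stats::rnorm(n1 * n2, 0, sd_k))
      }
      samples[, , n] <- page
    }
  })
  structure(list(samples = samples, sample_times = times, weights = weights,
                 noise_sigma = noise_sigma, sigma_per_sample = sigma_pt,
                 seed = seed, sequence = seq, species = species,
                 spectrometer = spectrometer,
                 normalization = sum(weights$weights) / weights$n_pe^weights$n_dims),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<kspace_series> %s  %dx%d k-space x %d spectral points  sigma %g  seed %s\n",
              x$sequence$mode, d[1], d[2], d[3], x$noise_sigma,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Persist / restore a k-space series
#'
#' Serializes the complex samples together with their acquisition metadata
#' (weighting, noise level, seed, sequence) to a single-file container.
#'
#' @param kspace a `kspace_series`.
#' @param path output file path.
#' @return `write_kspace` returns `path` invisibly; `read_kspace` the
#'   restored `kspace_series`.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "kspace_series"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "kspace_series")) stop_param("%s does not contain a kspace_series", path)
  x
}
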