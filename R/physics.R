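#' Spectrometer description
#'
#' Bundles the static field and the two observation frequencies of a
#' double-tuned \eqn{^1}H/\eqn{^2}H system, plus the \eqn{^2}H carrier
#' position in ppm. The deuterium/proton frequency ratio is checked against
#' the gyromagnetic-ratio ratio \eqn{\gamma(^2H)/\gamma(^1H) \approx 0.1535}.
#'
#' @param field_strength static field in tesla.
#' @param deuterium_frequency \eqn{^2}H observation frequency in MHz.
#' @param proton_frequency \eqn{^1}H observation frequency in MHz.
#' @param carrier_offset \eqn{^2}H carrier position in ppm.
#' @return An object of class `spectrometer_spec`.
#' @examples
#' spectrometer_spec()
#' @export
spectrometer_spec <- function(field_strength = 15.2,
                              deuterium_frequency = 99.77,
                              proton_frequency = 649.93,
                              carrier_offset = 2) {
  for (v in c(field_strength, deuterium_frequency, proton_frequency))
    if (!is_scalar_num(v) || v <= 0) stop_param("spectrometer frequencies and field must be positive scalars")
  if (!is_scalar_num(carrier_offset)) stop_param("carrier_offset must be a scalar (ppm)")
  ratio <- deuterium_frequency / proton_frequency
  if (ratio < 0.150 || ratio > 0.157)
    stop_param("deuterium/proton frequency ratio %.4f outside the physical range 0.150-0.157", ratio)
  structure(list(field_strength = field_strength,
                 deuterium_frequency = deuterium_frequency,
                 proton_frequency = proton_frequency,
                 carrier_offset = carrier_offset),
            class = "spectrometer_spec")
}

#' @export
print.spectrometer_spec <- function(x, ...) {
  cat(sprintf("<spectrometer_spec> %.1f T  nu(2H) = %.2f MHz  nu(1H) = %.2f MHz  carrier = %g ppm\n",
              x$field_strength, x$deuterium_frequency, x$proton_frequency, x$carrier_offset))
  invisible(x)
}

#' Deuterated species description
#'
#' A single \eqn{^2}H-bearing resonance: its chemical shift, relaxation
#' times, and the number of deuterons per molecule (used when translating
#' between molecular and \eqn{^2}H-equivalent concentrations).
#'
#' @param label species name, e.g. `"HDO"`.
#' @param chemical_shift position in ppm (0-10).
#' @param T1,T2 longitudinal/transverse relaxation times in seconds,
#'   `0 < T2 <= T1`.
#' @param enrichment_factor deuterons per molecule (1 for HDO, 2 for
#'   \[6,6'-2H2\]-glucose and \[3,3'-2H2\]-lactate).
#' @return An object of class `species_spec`.
#' @examples
#' species_spec("HDO", 4.7, T1 = 0.32, T2 = 0.03, enrichment_factor = 1)
#' @export
species_spec <- function(label, chemical_shift, T1, T2, enrichment_factor = 2) {
  if (!is.character(label) || length(label) != 1L) stop_param("label must be a single string")
  if (!is_scalar_num(chemical_shift) || chemical_shift < 0 || chemical_shift > 10)
    stop_param("chemical_shift must lie in [0, 10] ppm")
  if (!is_scalar_num(T1) || !is_scalar_num(T2) || T2 <= 0 || T2 > T1)
    stop_param("need 0 < T2 <= T1 (seconds); got T1=%s T2=%s", format(T1), format(T2))
  if (!is_scalar_num(enrichment_factor) || enrichment_factor <= 0)
    stop_param("enrichment_factor must be positive")
  structure(list(label = label, chemical_shift = chemical_shift,
                 T1 = T1, T2 = T2, enrichment_factor = enrichment_factor),
            class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("<species_spec> %-8s %4.2f ppm  T1 = %g s  T2 = %g s  %g 2H/molecule\n",
              x$label, x$chemical_shift, x$T1, x$T2, x$enrichment_factor))
  invisible(x)
}

#' Default DMI species set
#'
#' HDO, glucose and lactate at 4.7, 3.6 and 1.2 ppm. Relaxation defaults
#' (HDO 320/30 ms, glucose 60/30 ms, lactate 300/60 ms) are configuration
#' placeholders in the range reported for deuterated metabolites in vivo;
#' override them from a configuration file for quantitative work. An
#' optional natural-abundance fat resonance at 1.1 ppm can be appended.
#'
#' @param include_fat also return the ~1.1 ppm fat species.
#' @return A named list of [species_spec()] objects.
#' @export
default_species <- function(include_fat = FALSE) {
  sp <- list(
    HDO     = species_spec("HDO",     4.7, T1 = 0.320, T2 = 0.030, enrichment_factor = 1),
    glucose = species_spec("glucose", 3.6, T1 = 0.060, T2 = 0.030, enrichment_factor = 2),
    lactate = species_spec("lactate", 1.2, T1 = 0.300, T2 = 0.060, enrichment_factor = 2)
  )
  if (include_fat)
    sp$fat <- species_spec("fat", 1.1, T1 = 0.300, T2 = 0.050, enrichment_factor = 1)
  sp
}

#' Acquisition sequence description
#'
#' Shared timing/geometry of the two spectroscopic-imaging modes. ME-SSFP
#' encodes the spectral dimension with a train of same-polarity gradient
#' echoes (flyback rewinders between them); CSI-SSFP records a gradient-free
#' FID per phase-encode step and discards the first few filter-corrupted
#' points. All durations are milliseconds.
#'
#' @param mode `"ME_SSFP"` or `"CSI_SSFP"`.
#' @param TR repetition time (ms).
#' @param flip_angle excitation flip angle in degrees, in \[0, 180).
#' @param matrix_size in-plane encoding matrix, length-2 integer.
#' @param fov in-plane field of view in mm, length 2.
#' @param slice_thickness slice thickness in mm.
#' @param me list with `n_echoes`, `echo_spacing` (ms), `first_echo_time`
#'   (ms), `flyback_duration` (ms), `readout_bandwidth` (Hz).
#' @param csi list with `n_fid_points`, `dwell_time` (ms), `n_discard`.
#' @return An object of class `sequence_spec`.
#' @seealso [me_sequence()], [csi_sequence()] for the shipped defaults.
#' @export
sequence_spec <- function(mode = c("ME_SSFP", "CSI_SSFP"),
                          TR = 11.48, flip_angle = 60,
                          matrix_size = c(32L, 32L), fov = c(40, 40),
                          slice_thickness = 20,
                          me = list(n_echoes = 5L, echo_spacing = 2.1,
                                    first_echo_time = 2.1, flyback_duration = 0.257,
                                    readout_bandwidth = 20000),
                          csi = list(n_fid_points = 46L, dwell_time = 0.2,
                                     n_discard = 4L)) {
  mode <- match.arg(mode)
  if (!is_scalar_num(TR) || TR <= 0) stop_param("TR must be positive (ms)")
  if (!is_scalar_num(flip_angle) || flip_angle < 0 || flip_angle >= 180)
    stop_param("flip_angle must lie in [0, 180) degrees")
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 2L || any(matrix_size < 2L)) stop_param("matrix_size must be two integers >= 2")
  if (length(fov) != 2L || any(fov <= 0)) stop_param("fov must be two positive lengths (mm)")
  if (!is_scalar_num(slice_thickness) || slice_thickness <= 0) stop_param("slice_thickness must be positive (mm)")
  if (mode == "ME_SSFP") {
    with(me, {
      if (n_echoes < 1 || echo_spacing <= 0 || first_echo_time <= 0 || flyback_duration < 0 || readout_bandwidth <= 0)
        stop_param("invalid ME timing parameters")
      if (n_echoes * echo_spacing >= TR)
        stop_param("echo train (%g ms) must fit within TR (%g ms)", n_echoes * echo_spacing, TR)
    })
  } else {
    with(csi, {
      if (n_fid_points < 2 || dwell_time <= 0 || n_discard < 0)
        stop_param("invalid CSI parameters")
      if (n_discard >= n_fid_points)
        stop_param("n_discard (%d) must be smaller than n_fid_points (%d)", n_discard, n_fid_points)
    })
  }
  structure(list(mode = mode, TR = TR, flip_angle = flip_angle,
                 matrix_size = matrix_size, fov = fov,
                 slice_thickness = slice_thickness,
                 me = me, csi = csi),
            class = "sequence_spec")
}

#' @rdname sequence_spec
#' @param ... passed on to [sequence_spec()].
#' @export
me_sequence <- function(...) sequence_spec(mode = "ME_SSFP", ...)

#' @rdname sequence_spec
#' @export
csi_sequence <- function(...) sequence_spec(mode = "CSI_SSFP", ...)

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> %s  TR %.2f ms  flip %g deg  %dx%d  FOV %gx%g mm\n",
              x$mode, x$TR, x$flip_angle, x$matrix_size[1], x$matrix_size[2], x$fov[1], x$fov[2]))
  if (x$mode == "ME_SSFP")
    cat(sprintf("  %d echoes, spacing %.2f ms, flyback %.3f ms, BW %g Hz\n",
                x$me$n_echoes, x$me$echo_spacing, x$me$flyback_duration, x$me$readout_bandwidth))
  else
    cat(sprintf("  FID %d pts @ dwell %.2f ms, %d discarded\n",
                x$csi$n_fid_points, x$csi$dwell_time, x$csi$n_discard))
  invisible(x)
}

#' Chemical shift to frequency offset
#'
#' Converts a chemical shift in ppm to a frequency offset in Hz relative to
#' the carrier: `(shift - carrier) * nu(2H in MHz)`. One global sign
#' convention (`exp(+2i pi f t)` phase evolution for positive offsets) is
#' used by the simulator and the fitter alike.
#'
#' @param shift chemical shift(s) in ppm.
#' @param spectrometer a [spectrometer_spec()].
#' @return Offset(s) in Hz.
#' @examples
#' ppm_to_hz(4.7, spectrometer_spec())  # HDO, +269.379 Hz
#' @export
ppm_to_hz <- function(shift, spectrometer = spectrometer_spec()) {
  stopifnot(inherits(spectrometer, "spectrometer_spec"))
  (shift - spectrometer$carrier_offset) * spectrometer$deuterium_frequency
}

#' Balanced-SSFP steady-state amplitude
#'
#' On-resonance steady-state transverse magnetization of a phase-alternated
#' balanced SSFP sequence, as a fraction of the fully relaxed magnetization,
#' evaluated at the echo center TE = TR/2:
#' \deqn{A = \sin\alpha \frac{1 - E_1}{1 - (E_1 - E_2)\cos\alpha - E_1 E_2}\, E_2^{1/2},}
#' with \eqn{E_i = \exp(-TR/T_i)}. The off-resonance banding profile is not
#' modeled; per-species amplitudes enter the forward model and the
#' concentration calibration through this on-resonance form only.
#'
#' @param species a [species_spec()].
#' @param seq a [sequence_spec()] (TR in ms and flip angle are used).
#' @return Steady-state amplitude fraction in \[0, 1\].
#' @examples
#' ssfp_attenuation(default_species()$HDO, csi_sequence())
#' @export
ssfp_attenuation <- function(species, seq) {
  stopifnot(inherits(species, "species_spec"), inherits(seq, "sequence_spec"))
  if (seq$flip_angle < 0 || seq$flip_angle >= 180)
    stop_param("flip angle must lie in [0, 180) degrees")
  a <- seq$flip_angle * pi / 180
  TRs <- seq$TR / 1000
  E1 <- exp(-TRs / species$T1)
  E2 <- exp(-TRs / species$T2)
  amp <- sin(a) * (1 - E1) / (1 - (E1 - E2) * cos(a) - E1 * E2)
  amp * sqrt(E2)
}

#' Spectral phasor basis
#'
#' Matrix of unit-modulus phasors `exp(2i pi (f_m + psi) t_n)` used both to
#' synthesize multi-frequency signals and as the design matrix of the
#' least-squares species separation. Entry (n, m) couples sample time `n`
#' with species frequency `m`; a common field offset `psi` multiplies all
#' columns by the same time-dependent phase.
#'
#' @param times sample times in seconds (nonempty).
#' @param shifts_hz per-species frequency offsets in Hz.
#' @param field_offset common off-resonance in Hz.
#' @return Complex matrix, `length(times)` x `length(shifts_hz)`.
#' @export
spectral_basis <- function(times, shifts_hz, field_offset = 0) {
  if (length(times) < 1L) stop_param("times must be nonempty")
  exp(2i * pi * outer(times, shifts_hz + field_offset))
}
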