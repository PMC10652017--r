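# Shared fixtures: all inputs are generated in code.

dmi_spect <- spectrometer_spec()
dmi_species <- default_species()
dmi_shifts <- ppm_to_hz(c(4.7, 3.6, 1.2), dmi_spect)

# Long-run Bloch-rotation iteration for the phase-alternated balanced-SSFP
# steady state (on resonance, pulses about x), sampled at the echo center.
# Independent oracle for ssfp_attenuation().
bloch_ssfp_oracle <- function(T1, T2, TR_ms, flip_deg, n_iter = 5000) {
  a <- flip_deg * pi / 180
  TRs <- TR_ms / 1000
  E1 <- exp(-TRs / T1); E2 <- exp(-TRs / T2)
  My <- 0; Mz <- 1; s <- 1; Mxy_post <- 0
  for (i in seq_len(n_iter)) {
    aa <- s * a
    My2 <- My * cos(aa) + Mz * sin(aa)
    Mz2 <- -My * sin(aa) + Mz * cos(aa)
    Mxy_post <- abs(My2)
    My <- My2 * E2
    Mz <- Mz2 * E1 + (1 - E1)
    s <- -s
  }
  Mxy_post * sqrt(E2)
}

# Build frame_images directly from known amplitudes and field offsets: the
# per-voxel signal model with no sampling/reconstruction in between, so
# fitters can be checked against exact ground truth.
make_synthetic_frames <- function(rho_true, psi_true, times, seqd = csi_sequence(),
                                  species = dmi_species, noise = 0, seed = NULL) {
  n1 <- dim(rho_true)[1]; n2 <- dim(rho_true)[2]; S <- dim(rho_true)[3]
  shifts <- ppm_to_hz(vapply(species[seq_len(S)], `[[`, numeric(1), "chemical_shift"),
                      dmi_spect)
  fr <- array(complex(real = 0), c(n1, n2, length(times)))
  for (tt in seq_along(times))
    for (m in seq_len(S))
      fr[, , tt] <- fr[, , tt] + rho_true[, , m] * exp(2i * pi * (shifts[m] + psi_true) * times[tt])
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    fr <- fr + complex(real = stats::rnorm(length(fr), 0, noise),
                       imaginary = stats::rnorm(length(fr), 0, noise))
  }
  structure(list(frames = fr, sample_times = times, recon_size = n1,
                 sequence = seqd, species = species[seq_len(S)],
                 spectrometer = dmi_spect, weights = NULL,
                 noise_sigma = noise, seed = seed),
            class = "frame_images")
}

# Exhaustive field-offset grid search + linear solve: independent oracle
# for the IDEAL fit on noiseless voxels.
psi_grid_oracle <- function(d, times, shifts, step = 0.1) {
  B <- spectral_basis(times, shifts)
  P <- solve(Conj(t(B)) %*% B, Conj(t(B)))
  Q <- diag(length(times)) - B %*% P
  lim <- 1 / (2 * min(diff(times)))
  grid <- seq(-lim, lim, by = step)
  rn <- vapply(grid, function(p)
    sqrt(sum(abs(Q %*% (exp(-2i * pi * times * p) * d))^2)), numeric(1))
  psi <- grid[which.min(rn)]
  list(psi = psi, rho = P %*% (exp(-2i * pi * times * psi) * d))
}

# One weighted CSI-SSFP tube-phantom pass: simulate -> IDEAL -> calibrate,
# returning the flux-conserving glucose-tube concentration estimate (mM).
run_tube_recovery <- function(seed, phantom, noise_sigma = 0.05,
                              na = 8, base_reps = 12) {
  seqc <- csi_sequence()
  wq <- build_weight_table(32, na = na, base_reps = base_reps, n_dims = 2)
  ks <- simulate_kspace(phantom, seqc, wq, dmi_spect, dmi_species,
                        noise_sigma = noise_sigma, seed = seed)
  fr <- reconstruct_frames(ks, 64)
  psi0 <- deutrecon:::resample_map(phantom$b0_map, 64)
  fit <- ideal_fit(fr, psi_init = psi0)
  ref <- deutrecon:::resample_mask(phantom$roi_masks$reference_region, 64)
  conc <- calibrate_concentration(fit, ref, seqc, magnitude = FALSE)
  recover_tube_concentration(conc, phantom, "glucose")
}

# One abdominal run through simulate -> reconstruct -> RK-SpecRecon,
# returning the lactate detection statistics and reconstructed peak time.
run_abdominal_case <- function(scenario, seed, noise_sigma = 0.1, lambda = 5,
                               times = seq(0, 90, by = 7.5)) {
  seqc <- csi_sequence()
  wq <- build_weight_table(32, na = 20, base_reps = 6, n_dims = 2)
  ser <- make_abdominal_phantom(scenario, times = times, seed = seed)
  frames <- lapply(seq_along(times), function(i)
    reconstruct_frames(simulate_kspace(ser$frames[[i]], seqc, wq, dmi_spect,
                                       dmi_species, noise_sigma = noise_sigma,
                                       seed = seed * 1000 + i), 64))
  rs <- function(m) deutrecon:::resample_mask(m, 64)
  body <- rs(ser$roi_masks$body); nz <- rs(ser$roi_masks$noise_region)
  tum <- rs(ser$roi_masks$tumor)
  null_roi <- body & !tum & !rs(ser$roi_masks$kidney) & !rs(ser$roi_masks$bladder)
  psi0 <- deutrecon:::resample_map(ser$frames[[1]]$b0_map, 64)
  rk <- rk_specrecon(frames, psi_init = psi0, lambda = lambda, mask = body | nz)
  lac_maps <- lapply(rk$fits, function(f) f$rho[, , match("lactate", f$species)])
  det <- roi_detection(lac_maps, tum, null_roi, 40)
  lac_coh <- vapply(lac_maps, function(m) Mod(mean(m[tum])), numeric(1))
  in_win <- times >= 40 & times <= 70
  list(det_window = max(det$det[in_win]), det_all = det$det,
       peak_time = times[which.max(lac_coh)], times = times)
}
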