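test_that("frame reconstruction conserves energy and zero-fill values", {
  ph <- make_tube_phantom(seed = 5)
  w <- build_weight_table(32, na = 1, base_reps = 3, n_dims = 2)
  ks <- simulate_kspace(ph, csi_sequence(), w, dmi_spect, dmi_species, 0)
  fr64 <- reconstruct_frames(ks, 64)
  fr32 <- reconstruct_frames(ks, 32)
  Kn <- ks$samples[, , 1] / ks$normalization
  # Parseval bookkeeping of the synthesis convention
  expect_equal(sum(abs(fr64$frames[, , 1])^2), 64^2 * sum(abs(Kn)^2), tolerance = 1e-10)
  # zero-filling interpolates without changing original grid samples
  expect_equal(fr64$frames[seq(1, 64, 2), seq(1, 64, 2), 1], fr32$frames[, , 1],
               tolerance = 1e-10)
  # the image peak sits in the object
  pk <- which.max(abs(fr64$frames[, , 1]))
  expect_true(deutrecon:::resample_mask(ph$roi_masks$bath, 64)[pk])
  # all-zero k-space reconstructs to zero
  ks0 <- ks; ks0$samples[] <- 0
  expect_true(all(reconstruct_frames(ks0, 64)$frames == 0))
  expect_error(reconstruct_frames(ks, 16), "smaller")
  # uniform schemes of equal budget match in amplitude after normalization
  w2 <- build_weight_table(32, na = 1, base_reps = 12, n_dims = 2)
  ks2 <- simulate_kspace(ph, csi_sequence(), w2, dmi_spect, dmi_species, 0)
  expect_equal(reconstruct_frames(ks2, 64)$frames, fr64$frames, tolerance = 1e-12)
})

test_that("proton field maps scale to the deuterium frame", {
  expect_equal(proton_fieldmap_to_deuterium(0, dmi_spect), 0)
  expect_equal(proton_fieldmap_to_deuterium(100, dmi_spect), 100 * 99.77 / 649.93)
  expect_equal(round(proton_fieldmap_to_deuterium(100, dmi_spect), 3), 15.351)
  m <- outer(1:4, 1:5)
  expect_equal(proton_fieldmap_to_deuterium(m, dmi_spect),
               m * proton_fieldmap_to_deuterium(1, dmi_spect))
  expect_error(proton_fieldmap_to_deuterium(c(1, NA), dmi_spect), "finite")
})

test_that("IDEAL recovers amplitudes and field offsets exactly on noiseless data", {
  # single species on carrier, psi = 0: identity case
  t1 <- sample_times(me_sequence())
  rho1 <- array(complex(real = 3, imaginary = 1), c(4, 4, 1))
  sp <- list(species_spec("HDO", 2.0, T1 = 0.32, T2 = 0.03, enrichment_factor = 1))
  fr1 <- make_synthetic_frames(rho1, matrix(0, 4, 4), t1, me_sequence(), sp)
  f1 <- ideal_fit(fr1, psi_init = 0, mask_threshold = 0)
  expect_lt(max(abs(f1$rho - rho1)) / abs(rho1[1]), 1e-9)
  expect_lt(max(abs(f1$psi)), 1e-6)
  # 3 species, 5 ME echoes, psi_true = 25 Hz, psi_init = 0
  set.seed(7)
  n <- 4
  rho <- array(complex(real = stats::runif(n * n * 3, 1, 3),
                       imaginary = stats::rnorm(n * n * 3, 0, 0.2)), c(n, n, 3))
  fr <- make_synthetic_frames(rho, matrix(25, n, n), t1, me_sequence())
  fit <- ideal_fit(fr, psi_init = 0, psi_tolerance = 1e-4, max_iterations = 200,
                   mask_threshold = 0)
  expect_lt(max(abs(fit$rho - rho)) / max(abs(rho)), 1e-3)
  expect_lt(max(abs(fit$psi - 25)), 0.1)
  expect_true(all(fit$converged))
  fr_short <- make_synthetic_frames(rho1, matrix(0, 4, 4), t1[1:3], me_sequence(), sp)
  expect_error(ideal_fit(fr_short, species = dmi_species), "frames")
})

test_that("IDEAL matches the exhaustive psi-grid oracle on noiseless voxels", {
  set.seed(8)
  n <- 4   # 16-voxel instance
  t1 <- sample_times(me_sequence())
  rho <- array(complex(real = stats::runif(n * n * 3, 1, 3),
                       imaginary = stats::rnorm(n * n * 3, 0, 0.2)), c(n, n, 3))
  psi_true <- matrix(stats::runif(n * n, -40, 40), n)
  fr <- make_synthetic_frames(rho, psi_true, t1, me_sequence())
  fit <- ideal_fit(fr, psi_init = 0, psi_tolerance = 1e-3, mask_threshold = 0)
  for (v in seq_len(n * n)) {
    d <- vapply(seq_along(t1), function(k) fr$frames[, , k][v], complex(1))
    orc <- psi_grid_oracle(d, t1, dmi_shifts)
    expect_lt(abs(fit$psi[v] - orc$psi), 0.1)
    # the oracle's rho carries its own 0.1 Hz psi granularity (~1.5e-2 in rho)
    expect_lt(max(abs(fit$rho[, , ][v + (0:2) * n * n] - orc$rho)), 1.5e-2)
  }
})

test_that("aliased psi solutions resolve toward the initialization", {
  # the field-map seed decides between solutions one aliasing period apart
  t1 <- sample_times(me_sequence())
  alias <- 1 / min(diff(t1))
  rho <- array(complex(real = 2), c(2, 2, 3))
  fr <- make_synthetic_frames(rho, matrix(25, 2, 2), t1, me_sequence())
  f_lo <- ideal_fit(fr, psi_init = 25, mask_threshold = 0)
  f_hi <- ideal_fit(fr, psi_init = 25 + alias, mask_threshold = 0)
  expect_equal(mean(f_lo$psi), 25, tolerance = 1e-2)
  expect_equal(mean(f_hi$psi), 25 + alias, tolerance = 1e-2)
  # both are exact fits: residuals identical, species maps differ (the swap)
  expect_equal(mean(f_lo$residual), mean(f_hi$residual), tolerance = 1e-6)
})

test_that("residuals are orthogonal to the basis at convergence", {
  set.seed(9)
  t1 <- sample_times(csi_sequence())
  rho <- array(complex(real = stats::runif(12, 1, 3)), c(2, 2, 3))
  fr <- make_synthetic_frames(rho, matrix(10, 2, 2), t1, csi_sequence(), noise = 0.05, seed = 3)
  fit <- ideal_fit(fr, psi_init = 10, mask_threshold = 0)
  B <- fit$basis
  for (v in 1:4) {
    d <- vapply(seq_along(t1), function(k) fr$frames[, , k][v], complex(1))
    dem <- exp(-2i * pi * t1 * fit$psi[v]) * d
    r <- dem - B %*% vapply(1:3, function(m) fit$rho[, , m][v], complex(1))
    expect_lt(max(abs(Conj(t(B)) %*% r)), 1e-8)
  }
})

test_that("species-map noise scales with the inverse square root of the scan budget", {
  ph <- make_tube_phantom(seed = 10)
  seqc <- csi_sequence()
  noise_roi <- deutrecon:::resample_mask(ph$roi_masks$noise_region, 64)
  psi0 <- deutrecon:::resample_map(ph$b0_map, 64)
  sd_at <- function(reps) {
    w <- build_weight_table(32, na = 1, base_reps = reps, n_dims = 2)
    sds <- vapply(1:8, function(s) {
      ks <- simulate_kspace(ph, seqc, w, dmi_spect, dmi_species, 0.1, seed = 100 * reps + s)
      fit <- ideal_fit(reconstruct_frames(ks, 64), psi_init = psi0, mask = noise_roi)
      stats::sd(Re(fit$rho[, , 1][noise_roi]))
    }, numeric(1))
    mean(sds)
  }
  r <- sd_at(2) / sd_at(8)
  expect_equal(r, 2, tolerance = 0.15)
})

test_that("the 42-point CSI basis is better conditioned than the 5-echo ME basis", {
  Bme <- spectral_basis(sample_times(me_sequence()), dmi_shifts)
  Bcsi <- spectral_basis(sample_times(csi_sequence()), dmi_shifts)
  expect_lt(kappa(Bcsi, exact = TRUE), kappa(Bme, exact = TRUE))
})

test_that("kinetic regularization interpolates between frame-wise and pooled fits", {
  set.seed(11)
  n <- 6
  t1 <- sample_times(csi_sequence())
  rho <- array(complex(real = stats::rnorm(n * n * 3, 2, 0.5),
                       imaginary = stats::rnorm(n * n * 3, 0, 0.3)), c(n, n, 3))
  psi_true <- matrix(stats::runif(n * n, -15, 15), n)
  frs <- lapply(1:4, function(i)
    make_synthetic_frames(rho * (0.8 + 0.05 * i), psi_true, t1, csi_sequence(),
                          noise = 0.02, seed = 20 + i))
  # lambda = 0: identical to frame-wise IDEAL
  rk0 <- rk_specrecon(frs, psi_init = 0, lambda = 0, mask_threshold = 0)
  fw <- lapply(frs, ideal_fit, psi_init = 0, mask_threshold = 0)
  for (tt in 1:4) expect_equal(rk0$rho[, , , tt], fw[[tt]]$rho, tolerance = 1e-12)
  # lambda -> infinity approaches the pooled (time-averaged) fit
  rkB <- rk_specrecon(frs, psi_init = 0, lambda = 1e6, psi_tolerance = 1e-4,
                      mask_threshold = 0)
  pooled <- frs[[1]]
  pooled$frames <- Reduce(`+`, lapply(frs, `[[`, "frames")) / 4
  fp <- ideal_fit(pooled, psi_init = 0, psi_tolerance = 1e-4, mask_threshold = 0)
  for (tt in 1:4)
    expect_lt(max(abs(rkB$rho[, , , tt] - fp$rho)) / max(abs(fp$rho)), 2e-3)
  # temporal variance of the estimates is nonincreasing in lambda
  frs_c <- lapply(1:4, function(i)
    make_synthetic_frames(rho, psi_true, t1, csi_sequence(), noise = 0.1, seed = 40 + i))
  tempvar <- function(l) {
    rk <- rk_specrecon(frs_c, psi_init = 0, lambda = l, mask_threshold = 0)
    mean(apply(abs(rk$rho), 1:3, stats::var))
  }
  vs <- vapply(c(0, 0.1, 1, 10), tempvar, numeric(1))
  expect_true(all(diff(vs) <= 1e-12))
  expect_error(rk_specrecon(frs[1:2], lambda = -1, mask_threshold = 0), "lambda")
})
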