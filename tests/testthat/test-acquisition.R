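test_that("weight tables follow the quantized Hanning schedule", {
  # uniform mode: na = 1 recovers constant weights
  wu <- build_weight_table(32, na = 1, base_reps = 7, n_dims = 1)
  expect_true(all(wu$weights == 7))
  expect_equal(snr_gain_theoretical(wu), 1.0)
  # the study's weighted 1D schedule: center weight and budget bookkeeping
  w <- build_weight_table(32, na = 4, base_reps = 512, n_dims = 1)
  expect_equal(max(w$weights), 2048)
  expect_equal(w$weights[17], max(w$weights))   # DC index N/2 (0-based)
  expect_lt(abs(sum(w$weights) - 32 * 1024) / (32 * 1024), 0.05)
  # symmetry about the k-space center
  expect_equal(w$weights[17 + 1:15], w$weights[17 - 1:15])
  w2 <- build_weight_table(32, na = 8, base_reps = 12, n_dims = 2)
  expect_equal(w2$weights[17, 17], max(w2$weights))
  expect_equal(w2$weights[17 + 1:15, 17 + 1:15], w2$weights[17 - 1:15, 17 - 1:15])
  expect_true(all(w2$weights >= 1))
  expect_error(build_weight_table(1, 1, 1), "n_pe")
  expect_error(build_weight_table(32, 0.5, 1), "na")
})

test_that("spectral sample times implement the frame bookkeeping", {
  tc <- sample_times(csi_sequence())
  expect_length(tc, 42)
  expect_equal(tc[1], 0.0008)
  expect_equal(tc[42], 0.009)
  expect_equal(unique(round(diff(tc), 10)), 0.0002)
  tm <- sample_times(me_sequence())
  expect_length(tm, 5)
  expect_equal(tm, (2.1 * 1:5) / 1000)
  t0 <- sample_times(csi_sequence(csi = list(n_fid_points = 46L, dwell_time = 0.2,
                                             n_discard = 0L)))
  expect_length(t0, 46)
})

test_that("flyback duty cycle and scan budgets match the acquisition schedule", {
  expect_equal(flyback_duty_cycle(me_sequence()), 5 * 0.257 / 11.48)
  expect_equal(round(flyback_duty_cycle(me_sequence()), 4), 0.1119)
  no_fly <- me_sequence(me = list(n_echoes = 5L, echo_spacing = 2.1, first_echo_time = 2.1,
                                  flyback_duration = 0, readout_bandwidth = 20000))
  expect_equal(flyback_duty_cycle(no_fly), 0)
  dbl <- me_sequence(me = list(n_echoes = 5L, echo_spacing = 2.1, first_echo_time = 2.1,
                               flyback_duration = 2 * 0.257, readout_bandwidth = 20000))
  expect_equal(flyback_duty_cycle(dbl), 2 * flyback_duty_cycle(me_sequence()))
  expect_error(flyback_duty_cycle(csi_sequence()), "ME_SSFP")
  # uniform CSI and ME schedules both occupy ~6 min
  dur_csi <- scan_duration(build_weight_table(32, 1, 32, n_dims = 2), csi_sequence())
  dur_me <- scan_duration(build_weight_table(32, 1, 1024, n_dims = 1), me_sequence())
  expect_equal(dur_csi, dur_me)
  expect_equal(dur_csi, 32 * 32 * 32 * 11.48 / 1000)
})

test_that("simulated k-space is deterministic, linear, and correctly scaled", {
  ph <- make_tube_phantom(seed = 4)
  w <- build_weight_table(32, na = 1, base_reps = 4, n_dims = 2)
  seqc <- csi_sequence()
  k1 <- simulate_kspace(ph, seqc, w, dmi_spect, dmi_species, noise_sigma = 0.1, seed = 9)
  k2 <- simulate_kspace(ph, seqc, w, dmi_spect, dmi_species, noise_sigma = 0.1, seed = 9)
  expect_identical(k1$samples, k2$samples)
  # linearity at sigma = 0
  ph2 <- ph; ph2$species_maps <- lapply(ph$species_maps, function(m) 3 * m)
  ka <- simulate_kspace(ph, seqc, w, dmi_spect, dmi_species, 0)
  kb <- simulate_kspace(ph2, seqc, w, dmi_spect, dmi_species, 0)
  expect_equal(kb$samples, 3 * ka$samples, tolerance = 1e-12)
  # geometry error
  small <- make_tube_phantom(grid_shape = c(16L, 16L), seed = 1)
  expect_error(simulate_kspace(small, seqc, w, dmi_spect, dmi_species, 0), "exceeds")
  # weighted/uniform DC sample ratio equals the center-weight ratio
  wh <- build_weight_table(32, na = 8, base_reps = 12, n_dims = 2)
  kh <- simulate_kspace(ph, seqc, wh, dmi_spect, dmi_species, 0)
  expect_equal(Mod(kh$samples[17, 17, 1] / ka$samples[17, 17, 1]),
               wh$weights[17, 17] / w$weights[17, 17], tolerance = 1e-10)
})

test_that("noise statistics follow the summed-average model", {
  # all-zero phantom: per-sample variance must equal w * sigma_pt^2 per part
  ph0 <- deutrecon:::new_dmi_phantom(c(32L, 32L), c(40, 40),
                                     list(HDO = matrix(0, 32, 32)),
                                     matrix(0, 32, 32), list())
  sp <- list(species_spec("HDO", 4.7, T1 = 0.32, T2 = 0.03, enrichment_factor = 1))
  w <- build_weight_table(32, na = 1, base_reps = 7, n_dims = 1)
  ks <- simulate_kspace(ph0, me_sequence(), w, dmi_spect, sp, noise_sigma = 0.01, seed = 5)
  v <- c(Re(ks$samples), Im(ks$samples))
  n <- length(v)
  expected <- 7 * (0.01 * sqrt(20000 / 1000))^2
  # chi-square interval at alpha = 0.01 for the sample variance
  ci <- expected * stats::qchisq(c(0.005, 0.995), df = n - 1) / (n - 1)
  expect_gt(stats::var(v), ci[1])
  expect_lt(stats::var(v), ci[2])
})

test_that("noiseless k-space of a disk matches the analytic transform", {
  grid <- c(128L, 128L); fov <- c(40, 40); a <- 8
  cov <- deutrecon:::disk_coverage(grid, fov, c(0, 0), a)
  ph <- deutrecon:::new_dmi_phantom(grid, fov, list(HDO = 50 * cov),
                                    matrix(0, 128, 128), list())
  sp <- list(species_spec("HDO", 2.0, T1 = 0.32, T2 = 0.03, enrichment_factor = 1))
  seq1 <- me_sequence(me = list(n_echoes = 1L, echo_spacing = 2.1, first_echo_time = 2.1,
                                flyback_duration = 0.257, readout_bandwidth = 20000))
  w <- build_weight_table(32, 1, 1, n_dims = 1)
  S <- simulate_kspace(ph, seq1, w, dmi_spect, sp, 0)$samples[, , 1]
  A <- 50 * ssfp_attenuation(sp[[1]], seq1)
  kidx <- (1:32) - 1 - 16
  q <- sqrt(outer(kidx^2, kidx^2, "+")) / fov[1]
  arg <- 2 * pi * a * q
  K_an <- ifelse(arg == 0, A * pi * a^2 / prod(fov),
                 A * 2 * pi * a^2 / prod(fov) * besselJ(pmax(arg, 1e-12), 1) / pmax(arg, 1e-12))
  expect_lt(max(abs(S - K_an)) / abs(K_an[17, 17]), 0.01)
})

test_that("k-space containers round-trip through the persistence layer", {
  ph <- make_tube_phantom(seed = 4)
  w <- build_weight_table(32, na = 1, base_reps = 2, n_dims = 2)
  ks <- simulate_kspace(ph, csi_sequence(), w, dmi_spect, dmi_species, 0.05, seed = 2)
  f <- tempfile(fileext = ".rds")
  write_kspace(ks, f)
  ks2 <- read_kspace(f)
  expect_identical(ks$samples, ks2$samples)
  expect_equal(ks2$weights$na, 1)
  unlink(f)
})
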