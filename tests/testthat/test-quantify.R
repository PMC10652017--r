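test_that("SNR measurement recovers the known amplitude-to-noise ratio", {
  set.seed(12)
  n <- 120
  sig_roi <- matrix(FALSE, n, n); sig_roi[41:80, 41:80] <- TRUE
  noise_roi <- matrix(FALSE, n, n); noise_roi[1:30, ] <- TRUE
  A <- 5; sigma <- 0.7
  snrs <- vapply(1:30, function(i) {
    img <- complex(real = stats::rnorm(n * n, 0, sigma),
                   imaginary = stats::rnorm(n * n, 0, sigma))
    img <- matrix(img, n, n) + A * sig_roi
    measure_snr(img, sig_roi, noise_roi)
  }, numeric(1))
  expect_equal(mean(snrs), A / sigma, tolerance = 0.02)
  # zero-signal image: magnitude SNR sits at the Rayleigh mean/sd ratio, not 0
  zero_snrs <- vapply(1:30, function(i) {
    img <- matrix(complex(real = stats::rnorm(n * n, 0, sigma),
                          imaginary = stats::rnorm(n * n, 0, sigma)), n, n)
    measure_snr(img, sig_roi, noise_roi)
  }, numeric(1))
  rayleigh_ratio <- sqrt(pi / 2)
  expect_equal(mean(zero_snrs), rayleigh_ratio, tolerance = 0.05)
  # global scaling cancels
  img <- matrix(complex(real = stats::rnorm(n * n), imaginary = stats::rnorm(n * n)), n, n) +
    A * sig_roi
  expect_equal(measure_snr(3.7 * img, sig_roi, noise_roi),
               measure_snr(img, sig_roi, noise_roi))
  expect_error(measure_snr(img, sig_roi, sig_roi), "disjoint")
  expect_error(measure_snr(img, matrix(FALSE, n, n), noise_roi), "nonempty")
})

test_that("theoretical weighting gains hit the continuous limits and fall short when quantized", {
  expect_identical(snr_gain_theoretical("continuous-hanning", n_dims = 1), 2)
  expect_identical(snr_gain_theoretical("continuous-hanning", n_dims = 2), 4)
  expect_equal(snr_gain_theoretical(build_weight_table(32, 1, 10, n_dims = 1)), 1.0)
  g1 <- snr_gain_theoretical(build_weight_table(32, na = 4, base_reps = 512, n_dims = 1))
  expect_lt(g1, 2); expect_gt(g1, 1.8)
  g2 <- snr_gain_theoretical(build_weight_table(32, na = 8, base_reps = 12, n_dims = 2))
  expect_lt(g2, 4); expect_gt(g2, 3.5)
  # the continuous schedule evaluated as a table also reaches the limit
  wc <- build_weight_table(32, na = 2, base_reps = 8, n_dims = 1, quantize = FALSE)
  expect_equal(snr_gain_theoretical(wc), 2, tolerance = 1e-12)
})

test_that("Monte-Carlo image-domain gain agrees with the closed form", {
  g <- snr_gain_empirical(n_dims = 1, n_realizations = 60, seed = 3, n_boot = 40)
  expect_lt(abs(g$gain - 2), max(3 * g$se, 0.1))
})

test_that("concentration calibration is linear and anchored at the reference", {
  ph <- make_tube_phantom(seed = 13)
  seqc <- csi_sequence()
  w <- build_weight_table(32, na = 1, base_reps = 32, n_dims = 2)
  ks <- simulate_kspace(ph, seqc, w, dmi_spect, dmi_species, 0)
  fr <- reconstruct_frames(ks, 64)
  psi0 <- deutrecon:::resample_map(ph$b0_map, 64)
  fit <- ideal_fit(fr, psi_init = psi0)
  ref <- deutrecon:::resample_mask(ph$roi_masks$reference_region, 64)
  conc <- calibrate_concentration(fit, ref, seqc)
  # the reference region itself reads the reference value
  expect_equal(mean(conc$maps$HDO[ref]), 10, tolerance = 1e-6)
  # doubling all amplitudes doubles all concentrations at fixed calibration
  fit2 <- fit; fit2$rho <- 2 * fit$rho
  conc2 <- calibrate_concentration(fit2, ref, seqc,
                                   pre_injection_reference = fit$rho[, , 1])
  expect_equal(conc2$maps$glucose, 2 * conc$maps$glucose, tolerance = 1e-12)
  # ... but a global receiver gain cancels when the reference scales too
  conc3 <- calibrate_concentration(fit2, ref, seqc)
  expect_equal(conc3$maps$glucose, conc$maps$glucose, tolerance = 1e-12)
  # noiseless flux-conserving recovery of the 50 mM tubes
  concC <- calibrate_concentration(fit, ref, seqc, magnitude = FALSE)
  for (sp in c("HDO", "glucose", "lactate"))
    expect_equal(recover_tube_concentration(concC, ph, sp), 50, tolerance = 0.05)
  expect_error(calibrate_concentration(fit, ref & FALSE, seqc), "empty")
})

test_that("ROI time courses summarize kinetic concentration maps", {
  mk <- function(v) structure(list(maps = list(lactate = matrix(v, 8, 8)),
                                   calibration = list(), species = "lactate"),
                              class = "conc_maps")
  roi <- matrix(FALSE, 8, 8); roi[3:5, 3:5] <- TRUE
  tc <- roi_timecourse(lapply(c(1, 2, 4), mk), roi, times = c(0, 10, 20))
  expect_equal(tc$mean_mM, c(1, 2, 4))
  expect_equal(tc$integral_mM, 9 * c(1, 2, 4))
  expect_equal(attr(tc, "roi_size"), 9)
  expect_error(roi_timecourse(lapply(1, mk), roi & FALSE, 0), "empty")
})

test_that("limit of detection scales as the detection theory predicts", {
  expect_equal(estimate_lod(0, 1, 10), 0)
  expect_equal(estimate_lod(0.2, 1.5, 25), 2 * estimate_lod(0.1, 1.5, 25))
  expect_equal(estimate_lod(0.1, 1.5, 100), estimate_lod(0.1, 1.5, 25) / 2)
  # empirical detection crossing on synthetic maps with independent noise
  set.seed(14)
  n <- 64; sigma <- 0.5; cal <- 2
  roi <- deutrecon:::disk_coverage(c(n, n), c(40, 40), c(0, 0), 5) > 0.5
  noise_roi <- matrix(FALSE, n, n); noise_roi[1:12, ] <- TRUE
  lod <- estimate_lod(sigma, cal, sum(roi))
  det_rate <- function(conc_mM) {
    mean(vapply(1:60, function(i) {
      amp <- conc_mM / cal
      img <- matrix(complex(real = stats::rnorm(n * n, 0, sigma),
                            imaginary = stats::rnorm(n * n, 0, sigma)), n, n) + amp * roi
      measure_snr(img, roi, noise_roi, coherent = TRUE) >= 3
    }, logical(1)))
  }
  expect_gte(det_rate(2 * lod), 0.95)   # well above the LOD: detected
  expect_lte(det_rate(0.25 * lod), 0.4) # well below: mostly undetected
  expect_gte(det_rate(lod), 0.3)        # at the LOD: borderline by design
  expect_lte(det_rate(lod), 0.7)
})

test_that("field-strength sensitivity scaling follows the stated power law", {
  expect_equal(field_sensitivity_scaling(15.2, 15.2), 1.0)
  expect_equal(field_sensitivity_scaling(15.2, 7, exponent = 2), (7 / 15.2)^2)
  expect_equal(round(field_sensitivity_scaling(15.2, 7, 2), 3), 0.212)
  expect_equal(round(field_sensitivity_scaling(15.2, 7, 2.5), 3), 0.144)
  expect_error(field_sensitivity_scaling(-1, 7), "positive")
})

test_that("roi_detection calibrates against ROI-sized null samples", {
  set.seed(15)
  n <- 64
  body <- deutrecon:::disk_coverage(c(n, n), c(40, 40), c(0, 0), 17) > 0.5
  roi <- deutrecon:::disk_coverage(c(n, n), c(40, 40), c(8, 0), 4) > 0.5
  null_mask <- body & !roi
  maps <- lapply(1:6, function(i)
    matrix(complex(real = stats::rnorm(n * n, 0, 1),
                   imaginary = stats::rnorm(n * n, 0, 1)), n, n))
  d0 <- roi_detection(maps, roi, null_mask, 40)
  expect_true(all(d0$det < 5))       # no signal: no strong detections
  maps_sig <- lapply(maps, function(m) m + 3 * roi)
  d1 <- roi_detection(maps_sig, roi, null_mask, 40)
  expect_true(all(d1$det > 10))      # strong coherent signal detected
  expect_error(roi_detection(maps, roi, roi & FALSE, 40), "null mask")
})
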