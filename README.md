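# deutrecon

Simulation and reconstruction toolkit for **deuterium metabolic imaging
(DMI)** with balanced-SSFP spectroscopic imaging.

In DMI, injected [6,6'-²H₂]-glucose is followed through the ²H resonances of
water (HDO, 4.7 ppm), glucose (3.6 ppm) and [3,3'-²H₂]-lactate (1.2 ppm).
Warburg-driven lactate production highlights tumors, while inflamed tissue
takes up glucose without producing lactate — making the lactate channel a
discriminator between pancreatic cancer and pancreatitis. The measurements
are sensitivity-starved: lactate sits at sub-mM levels against a ~10 mM
natural-abundance water background. This package implements, end to end on
synthetic digital phantoms, the acquisition and processing chain used for
such experiments and the SNR theory behind its design choices:

- **Acquisition** — forward models of multi-echo SSFP (ME-SSFP: 5 gradient
  echoes, TE spacing 2.1 ms, flyback rewinders, one phase-encode axis) and
  FID-based CSI-SSFP (46-point FID at 5 kHz, first 4 points discarded, two
  phase-encode axes), with uniform or Hanning-weighted signal averaging and
  calibrated complex Gaussian noise.
- **Reconstruction** — zero-filled 2D FFT per spectral frame, followed by
  IDEAL iterative least squares: per voxel, the complex frame vector
  *d* is modeled as *d(t) = exp(2iπψt) Σₘ ρₘ exp(2iπfₘt)*, alternating an
  exact linear solve for the species amplitudes ρₘ with a Gauss–Newton
  update of the field offset ψ, seeded from a ¹H field map scaled by
  ν(²H)/ν(¹H). An optional kinetic-series mode (RK-SpecRecon style) adds a
  quadratic penalty λ Σₜ‖ρₜ − ρₜ₋₁‖² with ψ shared along the series.
- **Quantification** — conversion to mM against the ~10 mM
  natural-abundance HDO reference with per-species steady-state corrections
  *A = sin α (1−E₁)/(1−(E₁−E₂)cos α−E₁E₂)·√E₂*; ROI SNR and kinetic time
  courses; limits of detection; and the acquisition-weighting gain theory
  (continuous Hanning weighting yields exactly 2× per-voxel SNR for one
  weighted axis and 4× for two, at matched total scan time).
- **Phantoms** — a three-tube 50 mM validation phantom in a
  natural-abundance bath, and abdominal kinetic phantoms
  (tumor / pancreatitis / control) with gamma-variate glucose→HDO/lactate
  kinetics: lactate forms only in the tumor scenario and peaks 45–60 min
  after injection.

## Worked example

Run the shipped weighted CSI-SSFP tube-phantom pipeline (32×32 matrix,
40×40 mm FOV, TR 11.48 ms, flip 60°, weighting coefficient NA = 8 over 12
base repetitions):

```r
library(deutrecon)
cfg <- load_config(system.file("extdata", "default_config.yaml", package = "deutrecon"))
m <- run_pipeline(cfg, out_dir = "run_tubes")
str(m$metrics)
#> List of 3
#>  $ tube_mean_mM:List of 3
#>   ..$ HDO    : num 50
#>   ..$ glucose: num 48.4
#>   ..$ lactate: num 48.4
#>  $ snr         :List of 3
#>   ..$ tube_HDO    : num 159
#>   ..$ tube_glucose: num 367
#>   ..$ tube_lactate: num 232
#>  $ scan_minutes: num 4.74
```

The three 50 mM tubes are recovered at 48–50 mM after IDEAL separation and
natural-abundance calibration (the estimator integrates each tube over a
widened ROI because acquisition weighting blurs tube edges; see the methods
vignette). `run_tubes/` holds the species maps and field map as NIfTI, the
SNR table as CSV, and a JSON manifest keyed by the configuration hash and
seed. The weighting gain theory is available directly:

```r
snr_gain_theoretical("continuous-hanning", n_dims = 2)             # 4
snr_gain_theoretical(build_weight_table(32, na = 8, base_reps = 12,
                                        n_dims = 2))               # 3.97 (quantized)
```

For the kinetic scenarios use `inst/extdata/abdominal_config.yaml`
(`scenario: tumor` / `pancreatitis` / `control`); the manifest then reports
the tumor-ROI lactate peak time, its detection SNR against a matched
in-tissue null, and the binary detection outcome. A thin command-line
wrapper lives at `inst/cli/deutrecon.R`
(`phantom|simulate|reconstruct|quantify|snr-report|run`).

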