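---
title: "Models and methods behind deutrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deutrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deutrecon)
```

deutrecon simulates and reconstructs deuterium metabolic imaging (DMI)
experiments acquired with balanced-SSFP spectroscopic imaging. This
vignette explains the models, the parameters that matter, the design
decisions taken where the design was genuinely open, and what the
synthetic phantoms can and cannot say about real data.

## Signal physics

**Steady-state amplitudes.** Each species' transverse signal under
phase-alternated balanced SSFP is modeled by the on-resonance steady state
evaluated at the echo center (TE = TR/2),

$$A_m = \sin\alpha\,\frac{1-E_1}{1-(E_1-E_2)\cos\alpha - E_1E_2}\,\sqrt{E_2},
\qquad E_i = e^{-TR/T_{i,m}},$$

the fixed point of the per-TR rotation–relaxation map (the test suite
verifies agreement with a long-run Bloch iteration to better than 1e-6
relative). The off-resonance bSSFP banding profile is deliberately *not*
modeled: per-species amplitudes enter the forward model and the
concentration calibration through their \(T_1/T_2\) attenuation only,
which matches how such acquisitions are quantified in practice when the
echo spacing is tuned to the known shift structure. Shipped relaxation
defaults (HDO 320/30 ms, glucose 60/30 ms, lactate 300/60 ms) are
configuration placeholders of realistic magnitude, not measured values;
quantitative use of real data should override them in the YAML
configuration.

**Spectral model.** A voxel's spectral samples follow
\(d(t_n)=e^{2i\pi\psi t_n}\sum_m \rho_m e^{2i\pi f_m t_n}\) with
\(f_m=(\delta_m-\delta_{\mathrm{carrier}})\,\nu_{^2\mathrm{H}}\) in Hz
(carrier 2 ppm, \(\nu_{^2\mathrm{H}}\) in MHz) and a single global sign
convention (`exp(+2iπft)`) shared by simulator and fitter. ME-SSFP
provides 5 echo times at 2.1 ms spacing; CSI-SSFP provides the 42 FID
points that survive the 4-point digital-filter discard (0.8–9.0 ms at
0.2 ms dwell). Intra-readout \(T_2^*\) decay is not modeled — the retained
FID is short against the species' \(T_2\), and the same truncation
underlies the fitter's basis, keeping forward and inverse models
consistent.

## Acquisition and weighting

One acquisition is one TR: a full readout row at all echo times (ME-SSFP)
or one retained FID for a single phase-encode pair (CSI-SSFP). At the
default budgets (1024 repetitions × 32 lines for ME; 32 repetitions ×
32×32 pairs for CSI) both schedules occupy 32768 TRs ≈ 6.3 min, which is
the package's resolution of the per-line vs total ambiguity in repetition
counts: only the per-line reading reproduces the ~6 min scan time.

**Weighted averaging.** Averages are distributed over the phase-encode
axes as \(w(k)=\max\{1,\mathrm{round}(N_\mathrm{base}\cdot NA\cdot
H(k))\}\), where \(H\) is the raised-cosine window peaking at the k-space
center (separable in 2D) and \(NA\) is the weighting coefficient;
\(NA=1\) is the uniform scheme. Weighted lines are **summed, not
averaged**, so the window is imposed physically as an apodization, and
reconstruction applies one global normalization (total averages /
phase-encode count) so uniform schemes of equal budget match in
amplitude. For an object whose k-space energy concentrates near DC, the
per-voxel SNR gain over uniform averaging at matched budget is

$$G = \frac{w(0)\,N^d}{\sum_k w(k)},$$

which the continuous Hanning schedule attains exactly as \(G=2^d\) (the
window sums to \(N/2\) per axis): 2 for one weighted axis, 4 for two.
Quantized tables fall short (e.g. 3.97 for NA = 8 over 12 repetitions on a
32-point axis) because rounding and the floor of one average distort the
window — and the gain is object-dependent: structure away from the k-space
center is attenuated (blurring) rather than amplified.
`snr_gain_empirical()` verifies the closed form through the full
simulate/reconstruct pipeline on a smooth Gaussian phantom (σ = FOV/4, so
its spectrum spans well under one k-space sample).

**Noise.** Each acquisition adds i.i.d. circular complex Gaussian noise
per sample with standard deviation `noise_sigma` · √(BW/1 kHz), where BW
is the readout bandwidth (20 kHz for ME-SSFP, 1/dwell = 5 kHz for
CSI-SSFP). Referring `noise_sigma` to a fixed 1 kHz bandwidth makes
cross-sequence comparisons matched in noise spectral density, which is
what makes the uniform CSI/ME SNR ratio land near 1: CSI has 42/5 ≈ 8.4×
more spectral points per TR, ME has 4× the bandwidth and 32× more
repetitions per line; the products nearly cancel, with CSI keeping the
~10% edge that ME loses to flyback dead time (5 × 0.257 ms of every
11.48 ms TR, i.e. 11.2%).

## Reconstruction

Frames are reconstructed by centered zero-filling (32→64) and inverse
DFT in the synthesis convention \(i(x)=\sum_k K(k)e^{+2i\pi kx/N}\), which
preserves sample values under zero-filling and satisfies the Parseval
identity \(\sum|i|^2=N^2\sum|K|^2\) (asserted to 1e-10 in the tests). The
k-space center sits at 0-based index N/2 everywhere.

**IDEAL.** Because the field term \(e^{2i\pi\psi t}\) is unitary, the
amplitude solve for fixed ψ reduces to demodulating the data and
projecting onto one fixed basis — a variable-projection scheme that makes
the per-voxel iteration a matrix operation across all voxels. The ψ update
is the Gauss–Newton step of the unprojected residual; since re-solving the
amplitudes each iteration makes this a linearly contracting fixed point,
consecutive steps are Aitken-extrapolated, so the stopping rule
(default |Δψ| < 0.01 Hz, cap 50 iterations) reflects the true ψ error.
Voxels below 5% of the peak first-frame magnitude are skipped and
zero-filled; non-convergence flags the voxel rather than failing. Aliased
ψ solutions are spaced by 1/Δt (≈476 Hz for ME, 5 kHz for CSI); the fit
converges to the solution nearest its initialization, which is exactly why
a measured ¹H field map — scaled to the deuterium frame by
ν(²H)/ν(¹H) = 99.77/649.93 — seeds it. Complex amplitudes are fitted
without a nonnegativity constraint (phase carries through from B₀ and the
receiver); magnitudes are reported.

**Kinetic regularization.** For a kinetic series the package minimizes,
per voxel,
\(\sum_t\|d_t-A(\psi)\rho_t\|^2+\lambda\sum_{t\ge2}\|\rho_t-\rho_{t-1}\|^2\)
with ψ shared along the series; given ψ this is a block-tridiagonal linear
system solved exactly. λ = 0 dispatches to the frame-wise fit (exact
identity); λ → ∞ approaches the pooled time-average fit; the temporal
variance of the estimates is non-increasing in λ (all verified). The
quadratic first-difference penalty is this package's own definition of
kinetic regularization; the exported default is λ = 1, while the abdominal
configuration uses λ = 5, chosen once so that the 13-frame tumor lactate
course keeps a stable 45–60 min peak at the default noise level without
visibly biasing the curve toward its time average.

## Phantoms

**Three-tube phantom.** Three 5 mm tubes at 50 mM ²H (HDO, glucose,
lactate) on an 8 mm ring inside a 30 mm bath carrying the 10 mM
natural-abundance HDO background, on a 64×64 truth grid over the 40 mm
FOV; tube edges use sub-voxel coverage so their low-k spectra track the
continuous disk transform to <1%. The B₀ map is a seeded second-order
polynomial with ±30 Hz peak amplitude (²H frame) — smooth, as shimmed
fields are.

**Abdominal kinetic phantoms.** Body (34×26 mm ellipse), kidney, bladder
and tumor (10 mm) compartments with gamma-variate kinetics
\(c(t)=c_0+a\,[(\tau/t_p)^{t_p/\beta}e^{(t_p-\tau)/\beta}]\),
\(\tau=t-t_\mathrm{onset}\). Defaults (chosen once as qualitative matches,
since no numeric in-vivo curves are available): body HDO rises from the
10 mM baseline by 4 mM (peak 90 min), body glucose 6 mM peaking at 10 min,
kidney glucose earlier/stronger than bladder glucose (peaks ≈9 vs
≈40 min), and — in the tumor scenario only — tumor lactate of 1.5 mM
amplitude, onset 10 min, peaking ≈50 min, inside the 45–60 min window and
below the glucose level. Pancreatitis carries a mildly elevated glucose
curve but *no* lactate anywhere; control neither. Two built-in
consistency properties: the total labeled pool (glucose + lactate + HDO
increment, all in ²H-equivalent mM) is unimodal — after the uptake phase
label is only eliminated, never created — and integrated tumor-ROI lactate
exceeds the inflammation scenarios by far more than 10×.

What the generator does **not** emulate: respiratory motion and the blur
it causes, bSSFP banding, coil sensitivity profiles, intra-voxel spectral
overlap with the ≈1.1 ppm fat resonance (a fat species can be added to the
basis but is absent from the phantoms by default), perfusion-driven signal
phase, or 3D slab effects (the 20 mm slab is treated as a projected 2D
slice). Passing tests therefore demonstrate correctness of the
acquisition/reconstruction/quantification chain under its own stated
model, not robustness to those real-world effects.

## Quantification

**Calibration.** \(C_m(x)=\frac{|\rho_m(x)|}{A_m}\cdot\frac{10\,\mathrm{mM}\cdot
A_\mathrm{HDO}}{\langle|\rho^{pre}_\mathrm{HDO}|\rangle_\mathrm{ref}}\):
the pre-injection water amplitude over a reference region anchors the
receiver scale at the 10 mM natural abundance of tissue water, and each
species is corrected by its steady-state attenuation. The calibration is
linear and invariant to global receiver gain. The natural-abundance
reference is the SNR-limiting element — it is five-fold weaker than the
tubes — so the default tube-phantom noise (`noise_sigma = 0.05`, giving
tube SNRs of order 100 and per-frame reference SNR ≈ 6) was fixed once as
the regime where the reference stays well-conditioned; at several times
this noise the per-voxel ψ estimates in the reference region wander and
bias the water magnitude downward, a genuine failure mode of per-voxel
IDEAL at low SNR rather than a calibration defect.

**Tube recovery.** Acquisition weighting blurs tube edges (the cost of
the SNR gain), biasing a mean over the geometric tube mask low by ~30%.
Since the blur conserves the integral and the calibrated maps have unit DC
gain, `recover_tube_concentration()` sums the *complex* calibrated map
over a disk of twice the tube radius and divides by the true tube area,
subtracting any uniform background (the bath under the HDO tube). This
recovers 50 mM within ~2% on average at the default noise.

**Detection.** Weak-species detection uses the Rose criterion (SNR ≥ 3),
with two protocols. `measure_snr()` implements the classic
magnitude-ROI/noise-ROI measurement with the Rayleigh correction
(σ = sd(|noise|)/0.6551). For ROI-level lactate detection,
`roi_detection()` compares the phase-coherent tumor-ROI mean against the
spread of equally-sized disk ROIs placed in lactate-free tissue, pooled
over kinetic frames: reconstruction correlates neighbouring voxels and
field-map noise couples the strong resonances into weak channels inside
tissue, so a pure-noise background understates the null — the matched
in-tissue null absorbs both effects. The abdominal pipeline evaluates
detection inside a 40–70 min window around the physiologically expected
lactate peak. At the abdominal default noise (`noise_sigma = 0.1`) the
tumor scenario is detected with SNR ≈ 25–35 while pancreatitis/control
stay below 3 in ≥95% of runs; the corresponding limit of detection scales
as `detection_snr · σ · calibration / sqrt(ROI voxels)` and is
demonstrated as this self-consistency property — the absolute in-vivo
noise level needed to pin an absolute LOD is not available. Sensitivity
across field strengths follows \((B_0'/B_0)^{5/2}\): a quadratic intrinsic
dependence compounded by the halving of averages per unit time when TR
must nearly double to keep the resonances resolved at lower field.

## Numerical choices and problem sizes

Complex least squares use the normal equations of the 42×4 (or 5×4)
basis, whose condition numbers are ≈1.1 and ≈1.4 — far from
ill-conditioned; duplicate shifts are rejected. Degenerate inputs (zero
flip, vanishing \(T_2\), empty ROIs, overlapping tubes, mismatched grids)
raise descriptive errors rather than propagating NaNs. Monte-Carlo checks
in the tests and the acceptance script use 32–64 voxel grids, 50–200 noise
realizations, 100–150 pipeline repeats and 10+10 kinetic runs — sizes
chosen so each estimate's sampling error sits several times below the
tolerance it is checked against.

## Known limitations

Per-voxel IDEAL degrades ungracefully below per-frame SNR ≈ 2 (no spatial
regularization of ψ is implemented); the weighting gain statement applies
to smooth objects only; the kinetic penalty is quadratic and so smooths
genuine fast transients at large λ; NIfTI outputs carry voxel geometry but
no full affine orientation; and the CLI is a thin convenience wrapper, not
a scanner-facing interface.
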