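# Default deutrecon run configuration: weighted CSI-SSFP on the three-tube
# validation phantom. Acquisition values follow the study defaults; T1/T2
# are configuration placeholders (not measured values).
seed: 1
output_dir: deutrecon_out
scenario: tubes
noise_sigma: 0.05
spectrometer:
  field_strength: 15.2
  deuterium_frequency: 99.77
  proton_frequency: 649.93
  carrier_offset: 2.0
sequence:
  mode: CSI_SSFP
  TR: 11.48
  flip_angle: 60.0
  matrix_size: [32, 32]
  fov: [40.0, 40.0]
  slice_thickness: 20.0
  me:
    n_echoes: 5
    echo_spacing: 2.1
    first_echo_time: 2.1
    flyback_duration: 0.257
    readout_bandwidth: 20000.0
  csi:
    n_fid_points: 46
    dwell_time: 0.2
    n_discard: 4
species:
  - {label: HDO, chemical_shift: 4.7, T1: 0.320, T2: 0.030, enrichment_factor: 1}
  - {label: glucose, chemical_shift: 3.6, T1: 0.060, T2: 0.030, enrichment_factor: 2}
  - {label: lactate, chemical_shift: 1.2, T1: 0.300, T2: 0.060, enrichment_factor: 2}
phantom:
  grid_shape: [64, 64]
  tube_concentration: 50.0
  b0_inhomogeneity: 30.0
  times: [0, 15, 30, 45, 60, 75, 90]
weighting:
  na: 8
  base_reps: 12
recon:
  recon_size: 64
  psi_tolerance: 0.01
  max_iterations: 50
  kinetic_lambda: 1.0
  mask_threshold: 0.05
quantify:
  reference_value: 10.0
  detection_snr: 3.0
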