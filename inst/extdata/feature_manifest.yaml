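# Structural configuration of the 342-feature radiomic inventory.
# Category counts are determined by these parameters; the default
# configuration yields exactly 342 features.
levels: [8, 16, 24, 32, 48, 64]
glcm:
  distances: [1, 2, 3]
glrlm:
  modes: ["3d", "2d"]
glszm:
  modes: ["3d", "2d"]
ngtdm:
  distances: [1, 2, 3]
gabor:
  frequencies: [0.05, 0.10, 0.20, 0.30, 0.40]   # cycles / pixel, axial slices
  orientations_deg: [0, 45, 90, 135]
frequency:
  n_bands: 20                                    # radial 3D FFT bands
transforms:
  stats: ["energy_frac", "mean_abs", "sd", "entropy"]
descriptor:
  lbp_points: 8
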