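# Compact longitudinal phantom: mixed lesion dynamics, mild ventricular
# enlargement, small translational inter-scan motion.
shape: [64, 64, 48]
voxel_dims_mm: [1.0, 1.0, 1.0]
brain_semiaxes_mm: [26, 28, 20]
ventricle_centers_mm:
  - [-7, 5, 1]
  - [7, 5, 1]
ventricle_semiaxes_mm: [5, 11, 7]
expansion_factor: 1.08
lesions:
  - center: [10, 17, 1]
    baseline_cc: 1.5
    followup_cc: 1.5
    class: stable
  - center: [-15, -4, 5]
    baseline_cc: 1.0
    followup_cc: 0.4
    class: shrinking
  - center: [13, -10, -4]
    baseline_cc: 0.4
    followup_cc: 1.1
    class: growing
rotations_deg: [0.0, 0.0, 0.0]
translations_mm: [1.3, -0.8, 0.6]
noise_sd: 1.4
seed: 77
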