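# Synthetic asymmetric abdominal phantom (no real patient data).
# A large high-conductivity fluid pocket sits anterior-left of the tumor
# and a low-conductivity bone column posterior-right, so current driven
# by the straight anterior-posterior / left-right reference montage is
# shunted around the tumor while an obliquely rotated montage drives
# current through it. Used by the rotation-scan direction-of-effect
# checks. Generated into a voxel grid by generate_phantom(); the grid is
# fully determined by this file (seed included).
shape: [64, 64, 64]
spacing: [5.0, 5.0, 5.0]
body_semiaxes: [150.0, 105.0, 170.0]
organs:
- tissue: fluid
  center: [-55.0, 45.0, 0.0]
  semiaxes: [50.0, 40.0, 90.0]
  shape: ellipsoid
  shiftable: no
- tissue: bone
  center: [55.0, -45.0, 0.0]
  semiaxes: [24.0, 24.0, 10000.0]
  shape: zcylinder
  shiftable: no
- tissue: pancreas
  center: [0.0, 0.0, 0.0]
  semiaxes: [60.0, 25.0, 20.0]
  shape: ellipsoid
  shiftable: no
tumor_center: [0.0, 0.0, 0.0]
tumor_radius_mm: 22.0
asymmetry_mm: 0.0
jitter_mm: 0.0
seed: 1
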