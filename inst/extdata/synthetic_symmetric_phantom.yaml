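# Synthetic left-right symmetric abdominal phantom (no real patient
# data): spine column, paired kidneys and a centered pancreas/GTV, all
# mirror-symmetric about the mid-sagittal plane. The odd x-dimension
# puts a voxel-center column on the symmetry plane so the voxelization
# mirrors exactly; used by the +theta/-theta null checks.
shape: [49, 49, 49]
spacing: [6.5, 6.5, 6.5]
body_semiaxes: [150.0, 105.0, 170.0]
organs:
- tissue: bone
  center: [0.0, -60.0, 0.0]
  semiaxes: [18.0, 18.0, 10000.0]
  shape: zcylinder
  shiftable: no
- tissue: kidney
  center: [-65.0, -50.0, -25.0]
  semiaxes: [25.0, 22.0, 45.0]
  shape: ellipsoid
  shiftable: no
- tissue: kidney
  center: [65.0, -50.0, -25.0]
  semiaxes: [25.0, 22.0, 45.0]
  shape: ellipsoid
  shiftable: no
- tissue: pancreas
  center: [0.0, 5.0, 0.0]
  semiaxes: [65.0, 22.0, 18.0]
  shape: ellipsoid
  shiftable: no
tumor_center: [0.0, 5.0, 0.0]
tumor_radius_mm: 22.0
asymmetry_mm: 0.0
jitter_mm: 0.0
seed: 1
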