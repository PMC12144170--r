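# Femoral shaft non-union with a retained nail: revision adds an
# augmentative plate.
name: usecase3_plate_femur_analogue
kind: fe
regions: [nail, plate]
construct:
  bone_length: 200.0
  outer_radius: 14.0
  cortical_thickness: 5.0
  canal_radius: 6.0
  nail_radius: 5.0
  gap_width: 4.0
  noise_sd: 25.0
  voxel_spacing: 1.0
baseline: {}
revision:
  plate:
    length: 100.0
    width: 14.0
    thickness: 5.0
    angle_deg: 0.0
load:
  # hip joint force stand-in at mid-stance
  axial_n: -1800.0
  transverse_n: 200.0

cuboid_depth: 2.0
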