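# Humeral shaft non-union with a retained nail: revision adds an
# augmentative lateral plate over the fracture.
name: usecase2_plate_humerus_analogue
kind: fe
regions: [nail, plate]
construct:
  bone_length: 160.0
  outer_radius: 10.0
  cortical_thickness: 3.5
  canal_radius: 5.0
  nail_radius: 3.5
  gap_width: 4.0
  noise_sd: 25.0
  voxel_spacing: 1.0
baseline: {}
revision:
  plate:
    length: 80.0
    width: 12.0
    thickness: 4.0
    angle_deg: 0.0
load:
  # shoulder joint force stand-in during arm elevation
  axial_n: -350.0
  transverse_n: 100.0

cuboid_depth: 2.0
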