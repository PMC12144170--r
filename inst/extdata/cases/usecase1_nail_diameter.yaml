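# Tibial shaft non-union treated with an intramedullary nail: exchange
# of the 8 mm nail for an 11 mm nail without altering its position.
name: usecase1_nail_diameter
kind: fe
regions: [nail]
construct:
  bone_length: 200.0
  outer_radius: 12.0
  cortical_thickness: 4.0
  canal_radius: 5.5
  gap_width: 4.0
  noise_sd: 25.0
  voxel_spacing: 1.0
baseline:
  nail_radius: 4.0
revision:
  nail_radius: 5.5
load:
  # static peak joint load stand-in (walking, knee joint): axial
  # compression plus a transverse component producing bending at the gap
  axial_n: -1500.0
  transverse_n: 150.0

cuboid_depth: 2.0
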