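# Tibial fracture with an intramedullary nail under a torsion-dominant
# load: revision adds transverse strain-reduction screws bracketing the
# fracture gap.
name: usecase4_screw_torsion
kind: fe
regions: [nail]
construct:
  bone_length: 200.0
  outer_radius: 12.0
  cortical_thickness: 4.0
  canal_radius: 5.5
  nail_radius: 4.0
  gap_width: 4.0
  noise_sd: 25.0
  voxel_spacing: 1.0
baseline: {}
revision:
  screws:
    - {axial_offset: 10.0, axis: [1.0, 0.0, 0.0], radius: 2.0, length: 24.0}
    - {axial_offset: -10.0, axis: [1.0, 0.0, 0.0], radius: 2.0, length: 24.0}
load:
  # torque-dominant case: equilibrated force couple over the proximal
  # cuboid halves plus a modest axial component
  axial_n: -500.0
  transverse_n: 0.0
  torque_nm: 8.0
cuboid_depth: 2.0
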