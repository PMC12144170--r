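# Corrective osteotomy of a malaligned wrist: preoperative scene with a
# bony prominence impinging on the carpal unit during ulnar deviation;
# postoperative scene realigned (no prominence).
name: usecase5_wrist
kind: rom
scene:
  cup_radius: 32.0
  carpal_radius: 6.0
  carpal_offset: 24.0
  cup_half_angle: 60.0
  resolution: 36
baseline:
  prominence: {angle_deg: 25.0, half_width_deg: 5.0, height_mm: 4.0}
revision: {}
sweep:
  range: [-40.0, 40.0]
  step: 0.5
  eps: 0.0
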