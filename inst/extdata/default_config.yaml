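# Default synthetic comparison scenario: a lead-arm direct punch trial with
# soft-tissue-artifact marker corruption and a markerless-system emulation
# carrying a constant lead-shoulder flexion bias and a lead-elbow center
# offset of known magnitude, so the recovered agreement statistics can be
# checked against the injected values.
profile:
  sex: male
  height: 1.90
  mass: 78
script:
  punch_type: direct_face
  side: L
  repetitions: 4
  peak_hand_speed: 7.5
  duration_per_punch: 0.4
  guard_hold: 0.8
corruption:
  sta_amplitude: 0.010
  sta_amplitude_thorax: 0.005
  sta_bandwidth: 3
  jitter_sd: 0.0005
  # Calibration scenario: constant placement offsets are excluded because
  # they confound the injected inter-system bias being recovered.
  placement_offset_sd: 0
emulation:
  rate: 60
  angle_bias_deg:
    shoulder_L.flex_ext: 2.4
  center_offset_cm:
    elbow_L: [1.79, 1.79, 1.79]   # 3.1 cm in norm
  pose_noise_sd_deg: 0
  pose_noise_sd_m: 0
filter:
  order: 4
  cutoff: 8
cardan_sequence: zxy
front_side: L
marker_rate: 300
seed: 1
out_dir: boxkin_out
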