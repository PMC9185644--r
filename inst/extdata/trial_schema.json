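{
  "trial_csv": {
    "description": "One recording trial: comma-separated, one header line, fixed column order. Accelerations in m/s^2 (gravity +9.81 on vertical Z axes), angular rates in deg/s, timestamps in integer ms from trial start, FSR channels dimensionless (binary 0/1 unless analog emulation is enabled).",
    "sampling_rate_hz": 30,
    "columns": [
      "trunk_acc_z", "trunk_gyro",
      "l_acc_x", "l_acc_y", "l_acc_z", "l_gyro_x", "l_gyro_y", "l_gyro_z",
      "r_acc_x", "r_acc_y", "r_acc_z", "r_gyro_x", "r_gyro_y", "r_gyro_z",
      "t_ms", "l_fsr", "r_fsr"
    ]
  },
  "annotation_json": {
    "description": "Ground-truth gesture boundaries, one object per gesture. Intervals are half-open [onset_ms, onset_ms + duration_ms).",
    "fields": {
      "label": "one of left-forward, left-backward, right-forward, right-backward, forward, backward, clockwise, anticlockwise, or fpg-<base> for fake propulsions",
      "onset_ms": "gesture start in ms from trial start, >= 0",
      "duration_ms": "gesture length in ms, > 0",
      "left_active": "true when the left arm propels (or mimics propelling)",
      "right_active": "true when the right arm propels (or mimics propelling)",
      "fsr_active": "true for real propulsions (hand-rim contact), false for fake propulsions",
      "source": "fsr, manual or synthetic"
    }
  },
  "events_json": {
    "description": "Recognized propulsion events.",
    "fields": {
      "gesture_id": "canonical gesture number 1-8",
      "gesture": "gesture label",
      "onset_ms": "event start",
      "duration_ms": "event length"
    }
  }
}
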