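# vrgait run configuration template.
filter:
  order: 3          # Butterworth order
  cutoff_hz: 12     # low-pass cutoff, Hz
match_tolerance_s: 0.0333333333333333  # 3 samples at 90 Hz
outlier_k: 3.5      # MAD multiplier for offset outlier rejection
sync_offset_s: 0.0  # known reference-minus-tracker clock offset, s
# walkway_bbox: [0.0, 6.10, -0.305, 0.305]  # x_min, x_max, y_min, y_max (m)
detector:
  min_prominence: 0.01        # m
  min_peak_separation_s: 0.10 # s
  min_cycle_s: 0.4            # s
  max_cycle_s: 2.5            # s
heel_offsets:
  EU42: [-0.15, 0.00, -0.08]  # placeholder; see heel_offsets_template.yaml
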