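# Demo pipeline configuration for run_pipeline().
# Copy this file, point `trials` at your chamber-trial CSV (schema of
# write_chamber_trials()), and set `out_dir`. The packaged example trials
# are synthetic (generated by gen_chamber_series with known ground truth;
# see synthetic-trials.csv.truth.json).
trials: synthetic-trials.csv
out_dir: pipeline-out
seed: 42
scenario: scenario_A
system:
  room_volume: 7787      # m3
  nf_volume: 0.884       # m3, hemispherical near field, r = 0.75 m
  supply_air: 73.2       # m3/min
  beta: 10.6             # m3/min (boundary air speed 6 m/min)
  analyte: diacetyl
mc:
  n_iterations: 1000
  distributions:
    Q:
      kind: uniform
      lo: 65.9
      hi: 80.5
    G_grinding:
      kind: normal
      mean: 0.6
      sd: 0.0714         # 95% CI half-width 0.14 / 1.96
    G_packaging:
      kind: normal
      mean: 0.035
      sd: 0.1224         # 95% CI half-width 0.24 / 1.96, truncated > 0
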