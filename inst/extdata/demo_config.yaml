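# Bundled end-to-end demo: simulated four-group cohort with the default
# planted activation and correlation structure, analysed with the published
# edge-filter settings.
simulation:
  n_per_group: 7
seed: 20180817
section_policy: warn
posthoc_method: sidak
thresholds:
  r_min: 0.5
  p_max: 0.1
  n_min: 4
  drop_negative: true
output_dir: fosconnect_demo
log_level: info
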