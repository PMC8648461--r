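# Run configuration for `elastoscore run --config` / run_config(path).
# Anything omitted falls back to the package defaults shown in ?run_config.
seed: 1
out_dir: elastoscore_run
images: false
image:
  height: 64
  width: 64
  noise_sd: 0
rubric:
  visibility_threshold: 0.01
  uniform_threshold: 0.95
training:
  enabled: false
  hidden_size: 8
  epochs: 200
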