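# Example pipeline configuration (flat key-value; every key optional,
# defaults in habsuit::default_config()).
seed: 7
n_rows: 40
n_cols: 40
n_points: 120
n_background: 800
noise_sd: 0.05
t_high: 0.7
t_low: 0.4
fraction: 0.8
combine: min
allowed_classes: 1
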