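sample_types:
- SS
- CSS
- DF
- RJ
attributes:
- Brix
- Pol
- Fibre
- PolOfCane
- TRS
fraction: 0.75
splits: 10.0
trim_cutoff_low: 699.0
cv_trim_threshold: 5.0
sg_window: 11.0
sg_polyorder: 2.0
max_lv: 10.0
outlier_lv: 10.0
alpha: 0.05
n_perm: 19999.0
max_outlier_iter: 3.0
r2_method: pearson
seed: 7
generator_file: example_generator.yaml
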