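n_samples: 302
seed: 1
grid_low:
- 373.0
- 1011.0
- 5.0
grid_high:
- 1170.0
- 2222.0
- 5.0
param_names:
- Brix
- Pol
- Fibre
- PolOfCane
- TRS
param_means:
  Brix: 18.95
  Pol: 16.67
  Fibre: 13.29
  PolOfCane: 13.8
  TRS: 137.66
param_sds:
  Brix: 1.71
  Pol: 1.9
  Fibre: 1.79
  PolOfCane: 1.56
  TRS: 14.48
param_ranges:
  Brix:
    min: 13.08
    max: 23.42
  Pol:
    min: 10.78
    max: 21.2
  Fibre:
    min: 7.22
    max: 20.08
  PolOfCane:
    min: 8.4
    max: 17.56
  TRS:
    min: 86.94
    max: 173.8
target_corr:
  Brix:
    Brix: 1.0
    Pol: 0.97
    Fibre: 0.05
    PolOfCane: 0.94
    TRS: 0.94
  Pol:
    Brix: 0.97
    Pol: 1.0
    Fibre: 0.05
    PolOfCane: 0.97
    TRS: 0.96
  Fibre:
    Brix: 0.05
    Pol: 0.05
    Fibre: 1.0
    PolOfCane: 0.05
    TRS: 0.05
  PolOfCane:
    Brix: 0.94
    Pol: 0.97
    Fibre: 0.05
    PolOfCane: 1.0
    TRS: 0.99
  TRS:
    Brix: 0.94
    Pol: 0.96
    Fibre: 0.05
    PolOfCane: 0.99
    TRS: 1.0
constituent_bands:
  Brix:
  - center: 960.0
    width: 15.0
    intensity: 0.004
  - center: 1360.0
    width: 25.0
    intensity: 0.006
  - center: 2100.0
    width: 30.0
    intensity: 0.005
  Pol:
  - center: 960.0
    width: 15.0
    intensity: 0.003
  - center: 1139.0
    width: 20.0
    intensity: 0.005
  - center: 1600.0
    width: 25.0
    intensity: 0.006
  Fibre:
  - center: 1180.0
    width: 20.0
    intensity: 0.005
  - center: 1875.0
    width: 30.0
    intensity: 0.007
  PolOfCane:
  - center: 1139.0
    width: 20.0
    intensity: 0.004
  - center: 1600.0
    width: 25.0
    intensity: 0.005
  - center: 2100.0
    width: 30.0
    intensity: 0.004
  TRS:
  - center: 960.0
    width: 15.0
    intensity: 0.0005
  - center: 1360.0
    width: 25.0
    intensity: 0.0007
  - center: 2100.0
    width: 30.0
    intensity: 0.0006
background_bands:
- center: 1450.0
  width: 120.0
  intensity: 0.9
- center: 1940.0
  width: 140.0
  intensity: 1.1
- center: 1150.0
  width: 300.0
  intensity: 0.5
- center: 2100.0
  width: 200.0
  intensity: 0.6
- center: 850.0
  width: 250.0
  intensity: 0.35
sample_type_effects:
  SS:
    bands:
    - center: 1730.0
      width: 30.0
      intensity: 0.05
    noise_scale: 2.0
  CSS:
    bands:
    - center: 1450.0
      width: 40.0
      intensity: 0.04
    noise_scale: 1.5
  DF:
    bands:
    - center: 1930.0
      width: 40.0
      intensity: 0.03
    noise_scale: 1.2
  RJ:
    bands:
    - center: 1450.0
      width: 60.0
      intensity: 0.08
    - center: 550.0
      width: 80.0
      intensity: 0.06
    noise_scale: 1.0
noise_sd: 0.002
scatter_sd: 0.02
baseline_sd: 0.01
n_replicates: 9
reference_noise_sd: ~
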