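seed: 1
sites:
- label: Near
  distance_km: 0.0
- label: Edge
  distance_km: 5.0
- label: Remote
  distance_km: 60.0
varieties:
- cv_A
- cv_B
- cv_C
cv_noise: 0.1
n_replicates: 3
elements:
  Cu:
    source: 3500.0
    decay: 0.025
    partition:
    - 0.45
    - 0.18
    - 0.98
    - 0.11
    - 2.19
    - 0.06
    depth_slope: 1.0
    loq: 0.001
  Zn:
    source: 2800.0
    decay: 0.065
    partition:
    - 0.18
    - 1.02
    - 0.86
    - 0.05
    - 2.28
    - 0.33
    depth_slope: 1.0
    loq: 0.001
  Pb:
    source: 3600.0
    decay: 0.1
    partition:
    - 0.05
    - 1.16
    - 1.22
    - 0.09
    - 0.13
    - 0.3
    depth_slope: 1.0
    loq: 0.001
  Cd:
    source: 25.0
    decay: 0.08
    partition:
    - 0.58
    - 1.73
    - 0.68
    - 0.15
    - 0.11
    - 0.33
    depth_slope: 1.0
    loq: 0.001
  Ni:
    source: 25.0
    decay: 0.02
    partition:
    - 0.82
    - 1.12
    - 2.57
    - 0.2
    - 0.34
    - 0.14
    depth_slope: 1.0
    loq: 0.001
  Co:
    source: 20.0
    decay: 0.015
    partition:
    - 2.17
    - 2.28
    - 1.35
    - 0.11
    - 0.0
    - 0.0
    depth_slope: 1.0
    loq: 0.001
  As:
    source: 4.5
    decay: 0.015
    partition:
    - 1.3
    - 0.62
    - 2.23
    - 0.53
    - 0.07
    - 0.66
    depth_slope: 1.0
    loq: 0.001
  Cr:
    source: 2.5
    decay: 0.012
    partition:
    - 2.9
    - 0.23
    - 0.51
    - 0.24
    - 4.54
    - 0.85
    depth_slope: 1.0
    loq: 0.001
  Hg:
    source: 0.06
    decay: 0.003
    partition:
    - 0.6
    - 1.41
    - 1.93
    - 0.53
    - 0.02
    - 0.08
    depth_slope: 1.0
    loq: 0.001
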