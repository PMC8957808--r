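units:
- name: MeA
  area: MeA
  sign: +
  tau: 1.0
- name: Hip1
  area: vHIP
  sign: +
  tau: 1.0
- name: Hip2
  area: vHIP
  sign: +
  tau: 1.0
- name: lPBN
  area: lPBN
  sign: +
  tau: 1.0
- name: MDT
  area: MDT
  sign: +
  tau: 1.0
- name: Hyp1
  area: VMHvl
  sign: +
  tau: 1.0
- name: Hyp2
  area: VMHvl
  sign: +
  tau: 1.0
- name: HypIN1
  area: VMHvl
  sign: '-'
  tau: 1.0
- name: HypIN2
  area: VMHvl
  sign: '-'
  tau: 1.0
- name: Pyr1
  area: mPFC
  sign: +
  tau: 1.0
- name: Pyr2
  area: mPFC
  sign: +
  tau: 1.0
- name: Pv
  area: mPFC
  sign: '-'
  tau: 1.0
- name: Som1
  area: mPFC
  sign: '-'
  tau: 1.0
- name: Som2
  area: mPFC
  sign: '-'
  tau: 1.0
- name: Som3
  area: mPFC
  sign: '-'
  tau: 1.0
- name: dPag1
  area: dPAG
  sign: +
  tau: 1.0
- name: LS
  area: LS
  sign: '-'
  tau: 1.0
connections:
- pre: MeA
  post: Hyp1
  weight: 0.314
  plastic: yes
  w_min: 0.294
  w_max: 0.5
  alpha: 0.001
- pre: MeA
  post: Hyp2
  weight: 0.45
  plastic: yes
  w_min: 0.42
  w_max: 0.62
  alpha: 0.001
- pre: Hip1
  post: Hyp1
  weight: 0.199
  plastic: yes
  w_min: 0.179
  w_max: 0.36
  alpha: 0.001
- pre: Hip1
  post: Hyp2
  weight: 0.35
  plastic: yes
  w_min: 0.34
  w_max: 0.52
  alpha: 0.001
- pre: Hip2
  post: Hyp1
  weight: 0.199
  plastic: yes
  w_min: 0.179
  w_max: 0.36
  alpha: 0.001
- pre: Hip2
  post: Hyp2
  weight: 0.35
  plastic: yes
  w_min: 0.34
  w_max: 0.52
  alpha: 0.001
- pre: lPBN
  post: Hyp1
  weight: 1.5
- pre: Hyp1
  post: HypIN2
  weight: 0.9
- pre: HypIN2
  post: Hyp2
  weight: -1.5
- pre: Hyp2
  post: HypIN1
  weight: 0.9
- pre: HypIN1
  post: Hyp1
  weight: -0.2
- pre: MeA
  post: MDT
  weight: 2.0
- pre: MDT
  post: Pyr1
  weight: 1.23
  plastic: yes
  w_min: 0.4
  w_max: 1.4
  alpha: 0.0001
- pre: MDT
  post: Pyr2
  weight: 1.0
  plastic: yes
  w_min: 0.85
  w_max: 1.0
  alpha: 0.00075
  theta: 0.12
- pre: MDT
  post: Pv
  weight: 1.0
  plastic: yes
  w_min: 0.35
  w_max: 1.4
  alpha: 0.0005
- pre: Pv
  post: Pyr1
  weight: -1.3
- pre: Som1
  post: Pv
  weight: -1.2
- pre: Som1
  post: Pyr2
  weight: -2.0
- pre: Pyr1
  post: Som2
  weight: 1.0
- pre: Som2
  post: Pyr2
  weight: -2.6
- pre: Pyr2
  post: Som3
  weight: 1.0
- pre: Som3
  post: Pyr1
  weight: -0.4
- pre: Hyp1
  post: dPag1
  weight: 4.0
- pre: Pyr2
  post: dPag1
  weight: -0.9
  sign_exception: yes
- pre: LS
  post: Hyp1
  weight: -0.25
input_channels:
  conspecific:
  - unit: MeA
    gain: 1.0
  - unit: LS
    gain: 1.0
  context1:
  - unit: Hip1
    gain: 1.0
  context2:
  - unit: Hip2
    gain: 1.0
  defeat:
  - unit: lPBN
    gain: 1.0
  - unit: Som1
    gain: 1.0
plasticity:
  alpha: 0.0005
  theta: 0.5
  enabled: yes
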