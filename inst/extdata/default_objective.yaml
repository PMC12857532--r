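# Default constraint-scaled dose objective: weights, ideal doses,
# dose-volume constraints and per-constraint scaling factors.
structures:
- name: PTV
  weight: 50.0
  ideal: 1.0
  factor: 0.75
  constraints:
  - metric: Dcc
    arg: 2.0
    limit: 1.35
- name: bladder
  weight: 20.0
  ideal: 0.0
  factor: 0.5
  constraints:
  - metric: Vpct
    arg: 50.0
    limit: 40.0
- name: rectum
  weight: 20.0
  ideal: 0.0
  factor: 0.7
  constraints:
  - metric: Vpct
    arg: 50.0
    limit: 50.0
  - metric: Vpct
    arg: 80.0
    limit: 20.0
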