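# Demonstration scenario: post-surgery localization with peri-cavity
# chemoattractant injection at the strongest swept rate, followed by
# S-G2-M-targeting chemotherapy from t = 150 h.
t_end: 240
N_b: 47
N_init: 50
psi: [0.2, 0.0, 0.8]
injection:
  sites:
    - [5.8, 5.0]
    - [5.0, 5.8]
    - [4.2, 5.0]
    - [5.0, 4.2]
  windows:
    - [0, .inf]
  rate: 567
drug:
  start: 150
  rate: 22.7
  targeting: S-G2-M
fields:
  l_b_D: 22.7
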