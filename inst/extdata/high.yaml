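# High-toxicity scenario: delta_c = 34, close to the admissibility boundary
# delta_c/N <= 1 (the equilibrated epithelium retains ~34 cells).
mode: simulate
b: 10
d: [0.1, 0.11, 0.2, 0.9, 1]
delta_c: 34
solver:
  t_max: 250
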