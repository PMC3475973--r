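# Low-toxicity scenario: delta_c = 1 toxic particle per time unit into an
# epithelium starting at 100 cells (b = 10, d1 = 0.1).
mode: simulate
b: 10
d: [0.1, 0.11, 0.2, 0.9, 1]
delta_c: 1
solver:
  t_max: 250
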