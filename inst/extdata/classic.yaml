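# Phase-switching one-compartment comparison model: elimination speeds up
# after 20 time units of intoxication, exposure ends at t = 60.
mode: classic
classic:
  type: phase_switch
  variant: 1
  k_a1: 0.2
  k_e1: 0.05
  k_e2: 0.2
  switch_time: 20
  C_ext: 10
  depuration_start: 60
  times: {from: 0, to: 100, by: 0.5}
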