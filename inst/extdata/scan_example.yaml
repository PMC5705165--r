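# Reduced phase scan preset (a 2 x 3 corner of the published diagrams)
model:
  variant: ZS
  g: 0.2
solver:
  h: 0.16
  c: 0.02
  t_end: 25
grid:
  alpha: [0.5]
  v0: [2.5, 5.0]
  mu_tot: [0.39269908169872414, 2.356194490192345, 4.71238898038469]  # {0.125, 0.75, 1.5} pi
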