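# Rotating reference state of the zero-stress model
model:
  variant: ZS
  alpha: 0.5
  v0: 2.5
  mu_tot: 2.356194490192345   # 0.75 * pi
  g: 0.2
solver:
  h: 0.12
  c: 0.01
  t_end: 30
output:
  directory: actomotion_out
  stride: 500
  write_vtk: false
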