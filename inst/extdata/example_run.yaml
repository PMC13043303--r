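# Example run configuration for the depact command-line pipeline.
# All units are SI; unknown keys are rejected.
grid:
  shape: [128, 128]
  spacing: 0.0005          # 0.5 mm
medium:
  skull_rho: 1850          # kg/m^3
  skull_cp: 2800           # m/s
  skull_cs: 1250           # m/s
  water_temperature: 20    # deg C -> sound speed via water_sos()
  shell_inner_radius: 0.014
  shell_thickness: 0.0065
sensors:
  type: circle
  radius: 0.025
  n_elements: 256
solver:
  dt: 5.0e-8               # 50 ns
  nt: 640
  pml_thickness: 10
recon:
  method: iterative
  fc: 5.0e+5               # 0.5 MHz Butterworth cutoff
  n_outer: 10
seeds:
  phantom: 7
  noise: 8
paths:
  out: out
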