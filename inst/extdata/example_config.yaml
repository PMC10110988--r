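# Example methanobatch CLI configuration.
# Pressures in mBar, temperatures in degC, volumes in ml at this boundary;
# kinetic constants in SI (1/s, cells/mol, mol/s, mol/m3).

scenario:
  # either a named preset ...
  preset: series_1_1
  # ... optionally with overrides:
  overrides:
    initial_pressure_mbar: 600
  # or a fully inline scenario (used when 'preset' is absent):
  # total_volume_ml: 132.5
  # liquid_volume_ml: 47
  # temperature_C: 65
  # initial_pressure_mbar: 600
  # mu_max: 1.7e-4
  # yield_Y_H2: 4.1e12
  # decay_b: 3e-7
  # k_gw: 8e-2
  # initial_cell_density: 1.43e7
  # t_L: 10800
  # t_E: 21600
  # duration_s: 1.5e5

generate:
  sampling_interval_s: 600
  pressure_sigma_mbar: 5
  cell_sigma_log10: 0.3
  cell_counts: true

fit:
  free: [mu_max, yield_Y_H2, k_gw]
  species: 1
  multistart: 8
  pressure_sigma_mbar: 5
  cell_sigma_log10: 0.3

porous:
  porosity: 0.35
  water_saturation: 0.2
  specific_area_m2_m3: 47
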