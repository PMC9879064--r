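# Example run configuration: 500 um acellular ECM hydrogel on a 165 um
# PDMS membrane, severe-OSA-like cycling (60 events/h, 20%/0% O2).
schema_version: 1
seed: 1
output_dir: results
stack:
  layers:
    - name: membrane
      role: membrane
      thickness_um: 165
      D_cm2_s: 3.5e-5
      alpha_mol_cm3_atm: 1.1e-6  # PDMS alpha taken equal to water
    - name: hydrogel
      role: sample
      thickness_um: 500
      D_cm2_s: 1.87e-5
      alpha_mol_cm3_atm: 1.1e-6
      rho_cell_per_cm3: 0
  top_boundary:
    type: no_flux
schedule:
  events_per_hour: 60
  high_fraction: 0.20
  low_fraction: 0.0
  total_duration_s: 600
grid:
  dz_um: 10
solver:
  dt_s: 0.1
  theta: 1.0
sensor:
  t90_s: 2
  noise_sd_percent: 0.2
  sample_rate_hz: 1
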