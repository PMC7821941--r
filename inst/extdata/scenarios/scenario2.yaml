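operations:
  annual_production_mass: 121000000.0
  bioreactor_working_volume: 20.0
  operating_hours_per_year: 8760.0
  inoculum_fraction: 0.01
cellular:
  cell_volume: 5.0e-15
  cell_density: 1060.0
  achievable_cell_concentration: 95000000.0
  hours_per_doubling: 16.0
  maturation_time: 156.0
  glucose_consumption_per_cell: 2.07e-13
  oxygen_uptake_per_cell: 2.478e-12
  o2_steady_state_fraction: 0.02
media:
  glucose_concentration: 0.0267
  basal_media_cost: 10.0
  fgf2_concentration: 5.0e-05
  fgf2_cost: 1000000.0
  tgfb_concentration: 2.0e-06
  tgfb_cost: 80900000.0
  media_density: 1.0
  media_specific_heat: 4.184
  media_inlet_temperature: 20.0
  culture_temperature: 37.0
utility:
  natural_gas_price: 6.4
  gas_energy_content: 303.600000000000023
  turbine_efficiency: 0.35
  process_water_cost: 0.00026
  wastewater_cost: 0.00053
  heat_exchanger_efficiency: 0.9
  heat_per_mol_o2: 470.0
  acbm_specific_heat: 2.24
  acbm_outlet_temperature: 37.0
  acbm_chilled_temperature: 4.0
  oxygen_cost: 0.003
  oxygen_stoichiometry: 6.0
  o2_molar_volume: 25.449999999999999
labor:
  base_wage: 13.68
  labor_correction_factor: 1.75
  shifts_per_day: 3.0
  laborers_per_bioreactor: 1.0
finance:
  equipment_unit_cost: 50000.0
  scaling_exponent: 0.6
  cepci_adjustment: 1.29
  lang_factor: 2.0
  debt_fraction: 0.6
  loan_interest_rate: 0.04
  equity_interest_rate: 0.1
  repayment_period: 30.0
  fixed_manufacturing_fraction: 0.05
switches:
  solar_enabled: no
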