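country: Tanzania
base_year: 2021
profile:
  population: 61500000.0
  annual_births: 2150000.0
  baseline_nmr: 20.0
  life_expectancy: 66.0
  gdp_per_capita: 1099.0
  the_per_capita: 40.62
  ssnc_need_fraction: 0.1
  mean_admission_days: 7.0
monetisation:
  method: gdp_multiplier
  gdp_per_capita: 1099.0
  gdp_multiplier: 2.3
  vsl_year: 2401.0
  gdp_growth: 0.03
  discount_rate: 0.03
  labour_entry_age: 20.0
  productive_years: 46.0
cost_rules:
  discount_rate: 0.03
  markup_consumables: 0.1
  maintenance_rate: 0.03
scenarios:
- name: A
  new_fraction: 1.0
  renovation_cost_fraction: 0.2
  item_acquisition_fraction: 1.0
- name: B
  new_fraction: 0.5
  renovation_cost_fraction: 0.2
  item_acquisition_fraction: 0.5
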