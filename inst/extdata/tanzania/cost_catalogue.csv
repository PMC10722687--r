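item,category,kind,level,unit_cost_usd,quantity,useful_life_years
district_newborn_unit_block,infrastructure,setup,district,358000,1,20
district_ward_furniture_set,furniture_fixtures,setup,district,50000,1,5
district_device_set,devices,setup,district,40000,1,5
district_supplies_consumables,supplies_consumables,running,district,42000,1,NA
district_neonatal_medicines,medicines,running,district,18480,1,NA
district_data_qi_system,data_qi,running,district,8400,1,NA
regional_newborn_unit_block,infrastructure,setup,regional,1600000,1,20
regional_ward_furniture_set,furniture_fixtures,setup,regional,70000,1,5
regional_device_set,devices,setup,regional,275000,1,5
regional_supplies_consumables,supplies_consumables,running,regional,125100,1,NA
regional_neonatal_medicines,medicines,running,regional,44880,1,NA
regional_data_qi_system,data_qi,running,regional,61200,1,NA
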