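name,cause,effectiveness,affected_fraction,baseline_coverage,target_coverage
kangaroo_mother_care,prematurity,0.51,0.47,0.1,0.85
care_for_prematurity,prematurity,0.9,1,0.1,0.85
injectable_antibiotics_sepsis,sepsis,0.9,1,0.1,0.85
supportive_care_sepsis,sepsis,0.9,1,0.1,0.85
supportive_care_intrapartum,intrapartum,0.1,1,0.1,0.85
supportive_care_congenital,congenital,0.1,1,0.1,0.85
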