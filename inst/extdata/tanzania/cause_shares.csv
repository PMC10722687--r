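cause,share_of_deaths
prematurity,0.206959
sepsis,0.163172
intrapartum,0.141682
congenital,0.141682
other,0.346505
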