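level,bed_capacity,n_hospitals
district,40,146
regional,80,25
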