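year,fraction
2021,0.25
2022,0.3
2023,0.35
2024,0.4
2025,0.55
2026,0.6
2027,0.7
2028,0.85
2029,0.9
2030,1
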