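# ideocrop soil profile
texture = clay loam
pwp = 0.23000000000000001
fc = 0.39000000000000001
sat = 0.5
ksat = 125
tau = 0.75
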