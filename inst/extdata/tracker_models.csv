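model,attachment,mass_g
HQBG3621S,backpack,23
HQNG4625S,neck,30
HQNG4625P,neck,34
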