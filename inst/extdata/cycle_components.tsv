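component	isotope	energy_kcal_mol
hydr	H	-71.63
hydr	D	-71.20
inter	H	-82.31
inter	D	-82.73
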