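unit_length	class	count
1	monomer	29
2	dimer	70
3	trimer	37
4	tetramer	98
5	pentamer	16
6	hexamer	4
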