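ref_codon	edited_codon	count
CAC	TAC	9
CAT	TAT	19
CGC	TGC	12
CGT	TGT	30
ACA	ATA	4
ACC	ATC	2
ACG	ATG	7
ACT	ATT	4
CGG	TGG	32
TCA	TTA	77
TCC	TTC	34
TCG	TTG	52
TCT	TTT	48
CAG	TAG	1
CGA	TGA	3
CCA	TCA	8
CCC	TCC	10
CCG	TCG	3
CCT	TCT	20
CCA	CTA	49
CCC	CTC	8
CCC	TTC	8
CCG	CTG	36
CCT	CTT	22
CCT	TTT	14
CTC	TTC	5
CTT	TTT	12
GCC	GTC	1
GCG	GTG	7
GCT	GTT	2
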