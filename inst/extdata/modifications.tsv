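name	kind	monoisotopic_delta	C	H	N	O	S
Carbamidomethyl (C)	fixed_cys	57.02146	2	3	1	1	0
N-ethylmaleimide (C)	fixed_cys	125.04768	6	7	1	2	0
Oxidation (M)	variable	15.99491	0	0	0	1	0
Acetyl (Protein N-term)	variable	42.01057	2	2	0	1	0
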