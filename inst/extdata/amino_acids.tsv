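aa	name	monoisotopic_mass	C	H	N	O	S
G	Glycine	57.02146	2	3	1	1	0
A	Alanine	71.03711	3	5	1	1	0
S	Serine	87.03203	3	5	1	2	0
P	Proline	97.05276	5	7	1	1	0
V	Valine	99.06841	5	9	1	1	0
T	Threonine	101.04768	4	7	1	2	0
C	Cysteine	103.00919	3	5	1	1	1
L	Leucine	113.08406	6	11	1	1	0
I	Isoleucine	113.08406	6	11	1	1	0
N	Asparagine	114.04293	4	6	2	2	0
D	Aspartate	115.02694	4	5	1	3	0
Q	Glutamine	128.05858	5	8	2	2	0
K	Lysine	128.09496	6	12	2	1	0
E	Glutamate	129.04259	5	7	1	3	0
M	Methionine	131.04049	5	9	1	1	1
H	Histidine	137.05891	6	7	3	1	0
F	Phenylalanine	147.06841	9	9	1	1	0
R	Arginine	156.10111	6	12	4	1	0
Y	Tyrosine	163.06333	9	9	1	2	0
W	Tryptophan	186.07931	11	10	2	1	0
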