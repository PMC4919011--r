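genotype	phenotype	sd
000	-8.17	0.07
001	-7.58	0.09
010	-6.13	0.14
011	-6.24	0.07
100	-5.96	0.03
101	-7.70	0.11
110	-7.67	0.09
111	-8.45	0.06
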