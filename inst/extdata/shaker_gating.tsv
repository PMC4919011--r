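genotype	phenotype	sd
0000	-1.97	0.05
0001	-7.05	0.12
0010	-13.57	0.29
0011	-9.47	0.25
0100	-7.97	0.34
0101	-8.11	0.19
0110	-10.01	0.33
0111	-13.50	0.32
1000	-7.04	0.21
1001	-6.58	0.08
1010	-8.42	0.13
1011	-8.20	0.16
1100	-5.05	0.12
1101	-8.80	0.09
1110	-10.07	0.11
1111	-7.52	0.04
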