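SNP	CHR	POS	EA	OA	EAF	BETA	SE	P	N
rs66887589	4	120431000	C	T	0.48	0.16	0.02	2e-20	754581
rs10050092	4	120445000	C	T	0.34	-0.13	0.02	9e-13	754583
rs12646525	4	120470000	T	C	0.22	-0.1	0.02	7e-06	746319
rs80223330	4	120500000	A	G	0.14	0.1	0.03	1e-04	749960
rs17355550	4	120535000	C	T	0.03	-0.14	0.05	0.004	746320
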