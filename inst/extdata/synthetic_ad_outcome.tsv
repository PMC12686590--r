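SNP	CHR	POS	EA	OA	EAF	BETA	SE	P	N
rs66887589	4	120431000	C	T	0.478001181640264	0.00872320517054637	0.0130970163789711	0.505382196386911	54162
rs10050092	4	120445000	C	T	0.339223071526162	0.0123276601404	0.0138476798345421	0.373340843695242	54162
rs12646525	4	120470000	T	C	0.220394372438241	0.00761302838613943	0.0157573273541211	0.628994836075934	54162
rs80223330	4	120500000	A	G	0.141852221114434	-0.00287013865931015	0.0187411328128322	0.878282756634738	54162
rs17355550	4	120535000	C	T	0.029651785384587	-0.0204282179102257	0.0386700657897591	0.597312269014314	54162
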