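rsid	rs66887589	rs10050092	rs12646525	rs80223330	rs17355550
rs66887589	1	0.55	0.4	-0.2	0.1
rs10050092	0.55	1	0.5	-0.15	0.05
rs12646525	0.4	0.5	1	-0.1	0.15
rs80223330	-0.2	-0.15	-0.1	1	0.3
rs17355550	0.1	0.05	0.15	0.3	1
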