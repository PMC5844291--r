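gene	ts_mutant	mutation_site	temperature_c	cells_plated	revertants_obtained	revertants_sequenced	distinct_suppressors
cdc48	cdc48-353	G338D	37	3.8e8	358	30	19
eso1	eso1-H17	G799D	37	6e8	756	40	14
htb1	htb1-72	G52D	36	4.5e7	56	52	16
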