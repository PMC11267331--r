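sample_id	batch	condition	donor	replicate
term_UT_1	term	UT	d1	1
term_UT_2	term	UT	d2	2
term_UT_3	term	UT	d3	3
term_UT_4	term	UT	d4	4
term_TiO2_1	term	TiO2	d1	1
term_TiO2_2	term	TiO2	d2	2
term_TiO2_3	term	TiO2	d3	3
term_TiO2_4	term	TiO2	d4	4
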