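patient	gender	age_at_diagnosis	tumor_location	pT	pN	cM	G	p16	stage	surgery_adjuvant_rt	adjuvant_chemo	recurrence
M5.1	F	59	larynx	4a	2b	0	3	0	IVA	1	0	0
M6.1	M	81	oropharynx	2	0	0	2	0	I	1	0	0
M7.1	M	60	hypopharynx	2	2b	0	2	1	IVA	1	0	1
M9.1	M	54	oropharynx	2	1	0	2	1	I	1	1	1
M11.1	M	63	oropharynx	2	2	0	3	1	II	1	1	0
M12.1	M	49	larynx	4a	1	0	3	0	IVA	1	0	0
M14.1	M	62	larynx	4a	0	0	2	0	IVA	1	0	0
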