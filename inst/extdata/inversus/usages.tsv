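pub_key	name_key	name	locus	context	detail1	detail2	accepted	notes	common_name
Kingsley1880	1	Gelasimus smithii	p. 152	location	Zanzibar	.	chlorophthalmus	.	.
Alcock1900	1.1	Gelasimus inversus	p. 355	location	Karachi	.	inversa	.	.
Alcock1900	1.2	Gelasimus inversus	p. 355	citation	Kingsley1880	1	=	.	.
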