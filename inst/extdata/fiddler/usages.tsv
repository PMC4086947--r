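pub_key	name_key	name	locus	context	detail1	detail2	accepted	notes	common_name
Hess1865	1	Gelasimus vocans	p. 146	location	East Australia	.	vocans	.	.
Hess1865	2	Gelasimus signatus	p. 147	location	Sydney, Australia	.	signata	type description	.
King1924	1	Uca pugilator	p. 12	none	.	.	pugilator	no locality given; authors worked in San Francisco but the species is absent from the Pacific coast	fiddler crab
Macnae1966	1	Uca dussumieri	p. 75	location	Queensland, Australia	.	dussumieri	.	.
Macnae1966	2	Uca longidigitum	p. 75	location	Queensland, Australia	.	longidigitum	.	.
Macnae1966	3.1	Uca bellator	p. 76	location	Eastern Queensland, Australia	.	signata	.	.
Macnae1966	3.2	Uca bellator	p. 76	citation	Hess1865	2	=	.	.
Macnae1966	4	Uca unnamed sp. (pink claw)	p. 77	location	Queensland, Australia	.	polita	subsequently described as Uca polita	.
Macnae1966	5	Uca unnamed sp. (red legs)	p. 77	location	Darwin, Australia	.	flammula	subsequently recognized as Uca flammula	.
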