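species_id	binomial	status	etymology
signata	Uca signata	extant	.
dussumieri	Uca dussumieri	extant	named for J. J. Dussumier
longidigitum	Uca longidigitum	extant	Latin: long-fingered
polita	Uca polita	extant	Latin: polished
flammula	Uca flammula	extant	Latin: small flame
vocans	Uca vocans	extant	Latin: calling
pugilator	Uca pugilator	extant	Latin: boxer
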