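species_id	binomial	status	etymology
chlorophthalmus	Uca chlorophthalmus	extant	Greek: green-eyed
inversa	Uca inversa	extant	Latin: inverted
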