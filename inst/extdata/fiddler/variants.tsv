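variant	canonical	class
signatus	signata	gender-agreement
coarctatus	coarctata	gender-agreement
coartatus	coarctata	typographic
corctata	coarctata	typographic
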