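key	year	citation	recorded
Alcock1900	1900	Alcock, A. (1900). Materials for a carcinological fauna of India.	1
Kingsley1880	1880	Kingsley, J. S. (1880). Carcinological notes.	1
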