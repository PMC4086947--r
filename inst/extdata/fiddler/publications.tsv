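key	year	citation	recorded
Hess1865	1865	Hess, W. (1865). Beitraege zur Kenntniss der Decapoden-Krebse Ost-Australiens.	1
King1924	1924	King, F. & Siddall, A. (1924). A laboratory study of Uca pugilator.	1
Macnae1966	1966	Macnae, W. (1966). Mangroves in eastern and southern Australia.	1
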