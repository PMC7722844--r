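enzyme	site
NaeI	GCCGGC
BauI	CACGAG
EcoRI	GAATTC
HindIII	AAGCTT
HincII	GTYRAC
BamHI	GGATCC
PstI	CTGCAG
SmaI	CCCGGG
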