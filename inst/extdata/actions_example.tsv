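source	target	action	directed
TP53	MAPK3	activation	true
MAPK3	TP53	activation	true
AKT1	TP53	inhibition	true
AKT1	MAPK3	activation	true
SRC	AKT1	activation	true
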