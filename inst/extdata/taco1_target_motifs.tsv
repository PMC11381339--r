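gene	motif
COX2	DYGGL
ND4L	YGLDY
ND3	QTTN
ATP6	FASF
ATP6	PAA
ND6	VVV
ATP8	PWEP
ND1	PNP
COX3	PSPWPL
ND2	LPYNPN
ATP8	KWTKIC
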