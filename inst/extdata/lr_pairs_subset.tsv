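ligand	receptor
TNFSF12	TNFRSF12A
TNF	TNFRSF1A
TNFSF13B	TNFRSF13B
CXCL12	CXCR4
CCL2	CCR2
CCL5	CCR5
CCL19	CCR7
CXCL8	CXCR2
IL7	IL7R
IL15	IL2RB
IL34	CSF1R
CSF1	CSF1R
FLT3LG	FLT3
KITLG	KIT
TGFB1	TGFBR1
VEGFA	FLT1
HGF	MET
JAG1	NOTCH1
DLL1	NOTCH2
ICAM1	ITGAL
VCAM1	ITGA4
CD274	PDCD1
CD80	CTLA4
LGALS9	HAVCR2
ANGPT1	TEK
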