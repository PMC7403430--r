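gene1	gene2
TTTY15	USP9Y
AZGP1	GJC3
SLC45A3	ELK4
CTBS	GNG5
KANSL1	ARL17A
KANSL1	ARL17B
TFG	GPR128
CHIA	PIFO
SIDT2	TAGLN
HARS2	ZMAT2
NAIP	OCLN
PRIM1	NACA
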