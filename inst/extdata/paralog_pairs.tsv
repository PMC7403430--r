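gene1	gene2
HSPA1A	HSPA1B
SMN1	SMN2
DDX19A	DDX19B
CBWD1	CBWD2
NBPF10	NBPF14
GTF2H2	GTF2H2C
CYP2D6	CYP2D7
PMS2	PMS2CL
SRGAP2	SRGAP2B
FRG1	FRG1B
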