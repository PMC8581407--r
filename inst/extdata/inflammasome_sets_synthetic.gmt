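IC_CORE	synthetic stand-in inflammasome-signaling set	NLRP1	NLRP3	NLRC4	NLRP6	NLRP7	AIM2	PYCARD	CASP1	CASP4	CASP5	NAIP	MEFV	GSDMD	IL1B	IL18
CASP1_UP	synthetic stand-in inflammasome-signaling set	IL6	TNF	CXCL1	CXCL2	CXCL8	CCL2	CCL5	CCL20	IL1A	IL1RN	NFKB1	NFKB2	RELB	NFKBIA	TNFAIP3	SOD2	PTGS2	ICAM1	VCAM1	SELE	IRF1	IRF7	STAT1	STAT3
CASP1_DN	synthetic stand-in inflammasome-signaling set	SOCS3	OAS1	OAS2	OAS3	MX1	MX2	ISG15	IFIT1	IFIT2	IFIT3
GSDMD_UP	synthetic stand-in inflammasome-signaling set	IFI6	IFI27	IFI44	IFI44L	IFIH1	DDX58	RSAD2	USP18
GSDMD_DN	synthetic stand-in inflammasome-signaling set	HERC5	HERC6	XAF1	BST2	GBP1
IL1B_UP	synthetic stand-in inflammasome-signaling set	IL1B	GBP2	GBP4	GBP5	CXCL9	CXCL10	CXCL11	IDO1	IL15	IL18BP	TNFSF10	CASP7	CASP8	BID	BAX	BCL2A1	BIRC3	CFLAR	TRAF1	TLR2	TLR4	CD14	LCN2	S100A8	S100A9	SAA1	SAA2	C3	CFB	SERPINA3	LBP	HP	FGA	FGB	FGG	CRP	PLAU	PLAUR	MMP1	MMP3	MMP9	TIMP1	VEGFA	HIF1A	PTX3	CH25H	ZC3H12A	IER3	BCL3	TRIM21
IL1B_DN	synthetic stand-in inflammasome-signaling set	TRIM22	PARP9	PARP14	DTX3L	SP100	SP110	EPSTI1	LGALS9	SLAMF8	CD274	TNFSF13B	IL4I1	SECTM1	APOL1	APOL2	APOL3	UBE2L6	PSMB8	PSMB9	TAP1	TAP2	B2M
IL18_UP	synthetic stand-in inflammasome-signaling set	HLA-A	HLA-B	NMI	IFI35	STAT2	IRF9
IL18_DN	synthetic stand-in inflammasome-signaling set	ADAR	EIF2AK2
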