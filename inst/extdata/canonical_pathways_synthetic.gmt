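PI3K	synthetic illustrative membership	PIK3CA	PIK3CG	PIK3R1	AKT1	AKT2	PTEN	MTOR	PDPK1	EGFR	ERBB2	IGF1R	VEGFA	BCL2	BCL2L11	MCL1	FOXO3	TSC1	TSC2	RICTOR	KIT
MAPK	synthetic illustrative membership	KRAS	HRAS	NRAS	BRAF	RAF1	MAP2K1	MAP2K2	MAPK1	MAPK3	MAP3K2	EGFR	ERBB2	PDGFRA	FGFR1	MET	DUSP6	ELK1	JUN	FOS	SOS1
Cell_cycle	synthetic illustrative membership	CCND1	CCNE1	CDK4	CDK6	CDK2	RB1	E2F1	CDKN1A	CDKN1B	CDKN2A	TP53	MDM2	CCNB1	CDK1	WEE1	CHEK1	CHEK2	PLK1	AURKA	BUB1
Wnt	synthetic illustrative membership	WNT1	WNT3A	FZD1	LRP5	LRP6	DVL1	GSK3B	APC	AXIN1	AXIN2	CTNNB1	TCF7	LEF1	MYC	CCND1	SFRP1	DKK1	PORCN	RNF43	CSNK2A1
P53	synthetic illustrative membership	TP53	MDM2	MDM4	CDKN1A	BAX	PUMA	BBC3	GADD45A	SFN	RRM2B	SERPINB5	PERP	ZMAT3	SIVA1	TP53I3	PMAIP1	THBS1	SESN1	SESN2	ATM
Hippo	synthetic illustrative membership	STK3	STK4	SAV1	LATS1	LATS2	MOB1A	MOB1B	YAP1	WWTR1	TEAD1	TEAD2	CTGF	CYR61	AMOTL1	AMOTL2	NF2	FRMD6	TAOK1	MYC	AXIN1
TGFb	synthetic illustrative membership	TGFB1	TGFB2	TGFBR1	TGFBR2	SMAD2	SMAD3	SMAD4	SMAD7	BMP2	BMP4	BMPR1A	BMPR2	ACVR1	ID1	ID2	SERPINE1	SKP1	ZFYVE9	THBS1	ATM
Notch	synthetic illustrative membership	NOTCH1	NOTCH2	NOTCH3	NOTCH4	JAG1	JAG2	DLL1	DLL3	DLL4	RBPJ	HES1	HEY1	MAML1	ADAM17	PSEN1	PSEN2	NCSTN	APH1A	DTX1	LFNG
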