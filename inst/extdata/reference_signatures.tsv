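setting	gene
HCC	ABL2
HCC	ACSL4
HCC	AKR1B10
HCC	ATP6V1C1
HCC	BUB3
HCC	CASK
HCC	CCT3
HCC	CDKN2A
HCC	EIF3H
HCC	ENAH
HCC	FAM122B
HCC	FLVCR1
HCC	GBAP1
HCC	GPC3
HCC	HKDC1
HCC	HNRNPU
HCC	ICK
HCC	IGF2BP3
HCC	IRS1
HCC	LARS
HCC	LOC344887
HCC	LOC389834
HCC	MIB1
HCC	MRPL9
HCC	MTR
HCC	OTUD6B
HCC	PHF20L1
HCC	PRCC
HCC	PRKDC
HCC	PSMD4
HCC	PSPH
HCC	RAD21
HCC	RBM12B
HCC	ROBO1
HCC	RRM2B
HCC	SMARCC1
HCC	SMYD2
HCC	SMYD3
HCC	SRXN1
HCC	TCERG1
HCC	TERF1
HCC	TMEM106C
HCC	TMEM68
HCC	TSHZ2
HCC	TTC13
HCC	UBE2Q1
HCC	UBR5
HCC	UTP14A
HCC	VASH2
HCC	ZKSCAN3
HCC	ZNF260
HCC	ZNF623
HBV-HCC	CDKN2A
HBV-HCC	IGF2BP3
HBV-HCC	ZNF623
HCV-HCC	ABL2
HCV-HCC	ACSL4
HCV-HCC	AKR1B10
HCV-HCC	CCT3
HCV-HCC	CDKN2A
HCV-HCC	EIF3H
HCV-HCC	FLVCR1
HCV-HCC	GBAP1
HCV-HCC	GPC3
HCV-HCC	HKDC1
HCV-HCC	HNRNPU
HCV-HCC	IGF2BP3
HCV-HCC	LOC344887
HCV-HCC	MRPL9
HCV-HCC	MTR
HCV-HCC	PRCC
HCV-HCC	PRKDC
HCV-HCC	PSPH
HCV-HCC	RAD21
HCV-HCC	SMYD3
HCV-HCC	SQSTM1
HCV-HCC	SRXN1
HCV-HCC	TBC1D31
HCV-HCC	TBCE
HCV-HCC	TERF1
HCV-HCC	TMEM106C
HCV-HCC	TRIM31
HCV-HCC	TXNRD1
HCV-HCC	UBR5
HCV-HCC	VASH2
HCV-HCC	ZNF623
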