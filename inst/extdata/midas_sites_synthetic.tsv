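site	gene
MD01	WWOX
MD02	FHIT
MD03	NLGN1
MD03	EXOC4
MD04	PARD3B
MD05	DPP10
MD06	MYC
MD07	BCL2L1
MD07	TK1
MD08	ERBB2
MD09	LIN9
MD10	LIN37
MD11	CCND1
MD12	KRAS
MD13	EGFR
MD14	AKT3
MD15	GPC5
MD16	GPC6
MD17	FSTL4
MD17	SEMA5A
MD17	SNCAIP
MD18	PTEN
MD19	RB1
MD20	SMAD4
MD21	STK11
MD22	KEAP1
MD23	ARID1A
MD24	FAT1
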