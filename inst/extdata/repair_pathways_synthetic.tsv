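pathway	gene	esf
MMR	MLH1	3
MMR	MSH2	3
MMR	MSH6	2
MMR	PMS2	3
MMR	MSH3	1
MMR	MLH3	1
MMR	PMS1	1
MMR	EXO1	2
BER	APEX1	3
BER	XRCC1	3
BER	POLB	3
BER	LIG3	2
BER	OGG1	2
BER	MUTYH	2
BER	UNG	2
BER	PARP1	2
BER	NEIL1	1
BER	NTHL1	1
BER	SMUG1	1
BER	MBD4	1
NER	XPC	3
NER	XPA	3
NER	ERCC1	3
NER	ERCC2	3
NER	ERCC4	3
NER	ERCC5	3
NER	ERCC3	2
NER	DDB1	2
NER	DDB2	2
NER	GTF2H5	2
NER	CETN2	1
NER	RAD23B	1
TLS	POLH	3
TLS	POLK	3
TLS	REV1	3
TLS	REV3L	3
TLS	POLI	2
TLS	MAD2L2	2
TLS	RAD18	2
TLS	POLN	1
NHEJ	XRCC4	3
NHEJ	XRCC5	3
NHEJ	XRCC6	3
NHEJ	LIG4	3
NHEJ	PRKDC	3
NHEJ	NHEJ1	2
NHEJ	DCLRE1C	2
NHEJ	TP53BP1	2
NHEJ	POLL	1
NHEJ	POLM	1
HR	BRCA1	3
HR	BRCA2	3
HR	RAD51	3
HR	PALB2	3
HR	RAD54L	2
HR	BARD1	2
HR	BRIP1	2
HR	XRCC2	2
HR	XRCC3	2
HR	RAD51B	2
HR	RAD51C	2
HR	RAD52	1
MMEJ	POLQ	3
MMEJ	LIG1	2
MMEJ	FEN1	2
MMEJ	MRE11	2
MMEJ	NBN	2
MMEJ	RBBP8	2
MMEJ	XRCC1	2
MMEJ	PARP1	2
FA	FANCA	3
FA	FANCD2	3
FA	FANCI	3
FA	FANCL	3
FA	FANCC	3
FA	FANCG	3
FA	FANCB	2
FA	FANCE	2
FA	FANCF	2
FA	FANCM	2
FA	UBE2T	2
FA	FAAP24	1
DR	MGMT	3
DR	ALKBH2	2
DR	ALKBH3	2
checkpoint	ATR	3
checkpoint	ATM	3
checkpoint	CHEK1	3
checkpoint	CHEK2	3
checkpoint	TOPBP1	3
checkpoint	ATRIP	2
checkpoint	CLSPN	2
checkpoint	TIMELESS	2
checkpoint	TIPIN	2
checkpoint	RAD9A	2
checkpoint	RAD17	2
checkpoint	HUS1	2
checkpoint	RAD1	2
checkpoint	WEE1	2
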