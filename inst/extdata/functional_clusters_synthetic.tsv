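gene	cluster_id	cluster_label
WWOX	1	DNA replication and repair
FHIT	1	DNA replication and repair
TK1	1	DNA replication and repair
LIN9	1	DNA replication and repair
LIN37	1	DNA replication and repair
RB1	1	DNA replication and repair
CCND1	2	Cell cycle control
MYC	2	Cell cycle control
CDH13	2	Cell cycle control
BCL2L1	3	Cell survival and apoptosis
DAPK2	3	Cell survival and apoptosis
PDCD4	3	Cell survival and apoptosis
FAT1	3	Cell survival and apoptosis
TMEM173	4	Immune regulation
JAK2	4	Immune regulation
PTPRD	4	Immune regulation
ERBB2	5	Growth factor signaling
EGFR	5	Growth factor signaling
KRAS	5	Growth factor signaling
AKT3	5	Growth factor signaling
NF1	5	Growth factor signaling
ZEB1	6	Transcriptional regulation
FOXP1	6	Transcriptional regulation
SOX5	6	Transcriptional regulation
SMAD4	6	Transcriptional regulation
ARID1A	7	Chromatin organization
MACROD2	7	Chromatin organization
CTNNA3	8	Cell adhesion and migration
NEGR1	8	Cell adhesion and migration
CSMD1	8	Cell adhesion and migration
ROBO2	8	Cell adhesion and migration
MAGI2	8	Cell adhesion and migration
STK11	9	Metabolism
KEAP1	9	Metabolism
DPP10	9	Metabolism
PTEN	9	Metabolism
PRKN	10	Proteostasis
IMMP2L	10	Proteostasis
EXOC4	10	Proteostasis
RBFOX1	11	RNA processing
CCSER1	11	RNA processing
SNCAIP	11	RNA processing
AUTS2	12	Development and differentiation
EYS	12	Development and differentiation
GPC5	12	Development and differentiation
GPC6	12	Development and differentiation
SEMA5A	12	Development and differentiation
FSTL4	12	Development and differentiation
DMD	13	Neuronal signaling
LRP1B	13	Neuronal signaling
GRID2	13	Neuronal signaling
PDE4D	13	Neuronal signaling
NRXN3	13	Neuronal signaling
DLG2	13	Neuronal signaling
NLGN1	13	Neuronal signaling
PARD3B	13	Neuronal signaling
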