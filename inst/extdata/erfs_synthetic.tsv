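gene
WWOX
FHIT
MACROD2
DMD
CTNNA3
PRKN
LRP1B
NEGR1
IMMP2L
CCSER1
GRID2
PDE4D
NRXN3
CDH13
CSMD1
PTPRD
RBFOX1
DLG2
AUTS2
FOXP1
MAGI2
SOX5
ROBO2
EYS
TMEM173
DAPK2
JAK2
NF1
PDCD4
ZEB1
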