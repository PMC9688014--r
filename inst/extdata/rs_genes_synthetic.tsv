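gene
ATR
ATRIP
CHEK1
CLSPN
TIMELESS
TIPIN
RPA1
RPA2
RPA3
RAD17
RAD9A
RAD9B
RAD1
HUS1
TOPBP1
ETAA1
RFWD3
SMARCAL1
ZRANB3
HLTF
FBXO18
BLM
WRN
RECQL
RECQL4
RECQL5
MCM2
MCM3
MCM4
MCM5
MCM6
MCM7
MCM10
CDC45
GINS1
GINS2
GINS3
GINS4
PRIMPOL
POLA1
POLA2
PRIM1
PRIM2
POLD1
POLD2
POLD3
POLE
POLE2
PCNA
RFC1
RFC2
RFC3
RFC4
RFC5
FEN1
DNA2
EXO1
MUS81
EME1
SLX1A
SLX4
GEN1
RAD51
RAD51AP1
RAD52
RAD54L
BRCA1
BRCA2
PALB2
BARD1
FANCM
FANCD2
FANCI
USP1
WDR48
WEE1
CDC25A
CDC7
DBF4
CDC6
CDT1
ORC1
ORC6
GMNN
RRM1
RRM2
RRM2B
CHAF1A
CHAF1B
ASF1A
ASF1B
TONSL
MMS22L
ATAD5
WRNIP1
SPRTN
DTL
CUL4A
DDB1
PARP1
PARPBP
BOD1L1
ABRO1
FANCJ
SETD2
MDC1
RNASEH2A
RNASEH2B
RNASEH2C
RTEL1
PIF1
BRIP1
CDKN1A
CCNE1
CDK2
E2F1
MYBL2
FOXM1
LIN9
LIN37
LIN52
LIN54
RBBP4
TICRR
DONSON
DSCC1
CHTF18
POLQ
HELB
HROB
MCM8
MCM9
NUCKS1
NBN
MRE11
RAD50
RSR001
RSR002
RSR003
RSR004
RSR005
RSR006
RSR007
RSR008
RSR009
RSR010
RSR011
RSR012
RSR013
RSR014
RSR015
RSR016
RSR017
RSR018
RSR019
RSR020
RSR021
RSR022
RSR023
RSR024
RSR025
RSR026
RSR027
RSR028
RSR029
RSR030
RSR031
RSR032
RSR033
RSR034
RSR035
RSR036
RSR037
RSR038
RSR039
RSR040
RSR041
RSR042
RSR043
RSR044
RSR045
RSR046
RSR047
RSR048
RSR049
RSR050
RSR051
RSR052
RSR053
RSR054
RSR055
RSR056
RSR057
RSR058
RSR059
RSR060
RSR061
RSR062
RSR063
RSR064
RSR065
RSR066
RSR067
RSR068
RSR069
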