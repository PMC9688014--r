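priority	label	mh_min	mh_max	ins_min	ins_max	interchrom
1	NHEJ	NA	NA	1	NA	NA
2	NHEJ	0	1	NA	NA	NA
3	MMEJ	2	20	NA	NA	NA
4	SSA	21	NA	NA	NA	NA
5	unclassified	NA	NA	NA	NA	NA
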