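disease	lncrna	katzlda_rank	lrlslda_rank
Colon cancer	MALAT1	2	3
Colon cancer	HOTAIR	4	15
Colon cancer	KCNQ1OT1	7	6
Colon cancer	CRNDE	9	32
Colon cancer	LSINCT5	85	115
Gastric cancer	H19	1	1
Gastric cancer	CDKN2B-AS1	2	2
Gastric cancer	MEG3	3	4
Gastric cancer	PVT1	4	3
Gastric cancer	HOTAIR	7	18
Gastric cancer	UCA1	11	16
Gastric cancer	LSINCT5	107	116
Gastric cancer	SPRY4-IT1	109	100
Renal cancer	H19	1	1
Renal cancer	MEG3	3	4
Renal cancer	PVT1	4	3
Renal cancer	MALAT1	6	9
Renal cancer	GAS5	62	63
Renal cancer	KCNQ1OT1	71	111
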