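virus	group	POS	NEG	B
CMV	CPSNP	24	3	0
CMV	nonCPSNP	21	8	1
CMV	CTRL	3	1	0
EBV	CPSNP	27	0	0
EBV	nonCPSNP	29	0	1
EBV	CTRL	5	1	0
HSV1	CPSNP	20	7	0
HSV1	nonCPSNP	20	10	0
HSV1	CTRL	1	3	2
HSV2	CPSNP	13	12	2
HSV2	nonCPSNP	6	23	1
HSV2	CTRL	2	4	0
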