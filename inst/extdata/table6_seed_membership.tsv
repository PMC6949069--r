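gene	CGC	TGDB	ONGene	NCG
BARD1	1	0	1	0
BRCA1	1	1	0	1
BRCA2	1	1	0	1
RB1	1	1	0	1
TP53	1	1	0	1
AKT1	1	0	1	1
ARID1A	1	0	0	1
ARID1B	1	0	0	1
BAP1	1	0	0	1
CASP8	1	0	0	1
CCND1	1	1	1	1
CDH1	1	0	1	1
CDKN1B	1	0	1	1
CTCF	1	0	0	1
EP300	1	0	0	1
ERBB2	1	1	1	1
ESR1	1	1	0	1
FOXA1	1	0	0	1
GATA3	1	0	0	1
IRS4	1	0	0	1
MAP2K4	1	0	0	1
MAP3K1	1	0	0	1
MAP3K13	1	0	0	1
NCOR1	1	0	0	1
NOTCH1	1	0	0	1
NTRK3	1	0	0	1
PBRM1	1	0	0	1
PIK3CA	1	0	1	1
PPM1D	1	0	1	0
SMARCD1	1	0	0	1
TBX3	1	0	0	1
ZMYM3	1	0	0	1
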