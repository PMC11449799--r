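gene_symbol	n_studies
NRGN	12
CACNA1C	18
DRD2	15
NRXN1	9
MIR137	11
DGCR8	5
NOS1AP	4
TCF4	14
ZNF804A	10
GRIN2A	8
CALB1	2
LEF1	1
GLI3	1
SIX3	1
HTR7	3
KCNJ16	2
KCNIP4	3
AKT1	6
COMT	7
DISC1	5
RELN	6
GRM3	5
SP4	4
XRCC3	1
BCL11B	2
FOXP2	3
SATB2	4
CUL3	3
GRIA1	5
SLC39A8	4
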