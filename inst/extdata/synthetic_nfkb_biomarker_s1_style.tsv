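# SYNTHETIC stand-in for the published 108-gene NF-kB biomarker (S1-Table style).
# Shape matches the published signature (108 genes: 63 up, 45 down, mean
# |fold-change| >= 1.5, signed-linear convention); gene membership and
# fold-change values are illustrative, not the published list.
symbol	fold_change
EFNA1	12.4
TNFAIP3	9.56
NFKB2	9.18
RELB	7.74
NFKBIA	7.49
IL6	7.13
CXCL8	6.01
ICAM1	5.85
IRF1	5.71
TRAF1	5.49
ID1	-5.43
ID2	-4.27
CXCL1	4.25
CXCL2	4.22
CXCL3	4.12
CXCL10	4.11
ID3	-4.07
CCND2	-4.03
CCL2	3.91
MYB	-3.9
CCL20	3.79
BIRC3	3.77
TNIP1	3.57
SOD2	3.44
PTGS2	3.4
VCAM1	3.35
SELE	3.34
FOXM1	-3.29
BUB1	-3.27
IER3	3.17
JUNB	3.15
CCNA2	-3.12
CDC20	-3.05
CDK1	-3.03
PLAU	3.03
PLK1	-2.98
CD83	2.93
LTB	2.93
BCL3	2.9
REL	2.9
SGK1	2.87
ZFP36	2.79
KLF6	2.76
AURKB	-2.75
GADD45B	2.74
KIF11	-2.69
E2F1	-2.67
MKI67	-2.67
TOP2A	-2.67
PLK2	2.53
DUSP1	2.48
MCM2	-2.47
SAT1	2.44
TNF	2.43
IL1A	2.4
IL1B	2.38
MCM6	-2.33
PCNA	-2.33
IL32	2.31
RRM2	-2.28
CSF1	2.26
TYMS	-2.24
CDC6	-2.2
CDT1	-2.19
CSF2	2.14
GINS1	-2.12
LIF	2.12
ORC6	-2.08
EDN1	2.07
F3	2.05
ESPL1	-2.03
PLAUR	2.02
SERPINB2	1.98
NDC80	-1.95
SPC25	-1.95
MAP3K8	1.94
TNFAIP2	1.93
TTK	-1.92
TNFAIP8	1.9
ANLN	-1.83
ASPM	-1.83
UBE2C	-1.83
OPTN	1.82
DLGAP5	-1.8
HMMR	-1.79
NFKBIE	1.75
KIF20A	-1.73
KIF23	-1.72
IER2	1.71
KLF4	1.7
NUSAP1	-1.7
PRC1	-1.68
MMP9	1.67
RACGAP1	-1.67
CX3CL1	1.66
TLR2	1.65
TPX2	-1.63
CENPF	-1.62
CD69	1.61
CEP55	-1.61
FAM83D	-1.61
MELK	-1.59
SHCBP1	-1.57
IL15RA	1.56
ABCA1	1.54
STAT5A	1.53
B4GALT1	1.52
NINJ1	1.51
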