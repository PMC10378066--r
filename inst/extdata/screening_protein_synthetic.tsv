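feature	log2_fc	p_adj	layer
CXCL12	-2.20	0.0004	protein
ENPP2	-1.80	0.0009	protein
FBLN5	-1.55	0.0020	protein
FGF2	-1.30	0.0031	protein
LYVE1	-1.90	0.0007	protein
PDGFRB	-1.25	0.0044	protein
SERPINF1	-1.70	0.0012	protein
TIMP2	-1.15	0.0062	protein
TIMP3	-1.60	0.0016	protein
MMP2	-1.20	0.0055	protein
MMP9	1.35	0.0028	protein
COL18A1	-1.45	0.0022	protein
ANG	-1.10	0.0074	protein
HGF	-1.28	0.0039	protein
MET	1.18	0.0058	protein
CTGF	-1.52	0.0019	protein
CYR61	-1.40	0.0026	protein
ESM1	1.62	0.0013	protein
ENG	-1.22	0.0047	protein
NID1	-1.33	0.0035	protein
LAMA4	-1.48	0.0023	protein
SPARC	-1.12	0.0069	protein
VEGFA	0.70	0.0800	protein
FLT1	-0.85	0.1200	protein
KDR	-0.95	0.0300	protein
ANGPT1	-0.60	0.3400	protein
THBS1	-0.90	0.0700	protein
PECAM1	-0.55	0.4100	protein
TIE1	-0.80	0.1600	protein
NRP1	-0.75	0.2100	protein
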