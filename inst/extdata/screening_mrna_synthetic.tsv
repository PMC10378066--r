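feature	log2_fc	p_adj	layer
CXCL12	-3.10	0.0002	mrna
ENPP2	-2.70	0.0004	mrna
FBLN5	-2.35	0.0011	mrna
FGF2	-2.10	0.0008	mrna
LYVE1	-2.90	0.0003	mrna
PDGFRB	-1.95	0.0015	mrna
SERPINF1	-2.50	0.0006	mrna
TIMP2	-1.80	0.0021	mrna
TIMP3	-2.60	0.0005	mrna
ANGPT1	-1.90	0.0030	mrna
ANGPT2	1.75	0.0042	mrna
VEGFC	-1.70	0.0051	mrna
FLT1	-1.85	0.0027	mrna
KDR	-2.05	0.0019	mrna
PGF	1.95	0.0036	mrna
THBS1	-2.15	0.0024	mrna
EFNB2	-1.72	0.0060	mrna
PECAM1	-1.66	0.0071	mrna
CDH5	-1.78	0.0049	mrna
TIE1	-2.20	0.0018	mrna
COL4A3	-1.69	0.0083	mrna
VEGFA	0.90	0.0400	mrna
HGF	-1.20	0.0600	mrna
MMP2	-1.40	0.0150	mrna
MMP9	1.10	0.2200	mrna
ANG	-0.80	0.3100	mrna
ENG	-1.30	0.0120	mrna
NRP1	-1.45	0.0200	mrna
TEK	-1.35	0.0450	mrna
IL8	1.20	0.0900	mrna
LEP	1.05	0.1800	mrna
CSF3	-0.60	0.5200	mrna
FST	-0.75	0.4400	mrna
SPARC	-1.10	0.1100	mrna
NID1	-0.95	0.2600	mrna
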