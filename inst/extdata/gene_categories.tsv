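gene	category
HLA-A	immune
HLA-B	immune
TAP1	immune
TAP2	immune
B2M	immune
TLR4	immune
IL7R	immune
JAK1	immune
STAT1	immune
IRF1	immune
CD8A	immune
NLRP3	immune
TNF	immune
IFNGR1	immune
MYD88	immune
CDK4	cell_cycle
CDK6	cell_cycle
CCNE1	cell_cycle
CDC25A	cell_cycle
E2F1	cell_cycle
WEE1	cell_cycle
MTOR	proliferation
AKT1	proliferation
MAPK1	proliferation
RAF1	proliferation
GRB2	proliferation
IGF1R	proliferation
BRCA1	dna_repair
ATM	dna_repair
ATR	dna_repair
MLH1	dna_repair
MSH2	dna_repair
RAD51	dna_repair
XRCC1	dna_repair
CDH1	adhesion
CTNNB1	adhesion
ITGB1	adhesion
LAMA3	adhesion
COL17A1	adhesion
DSG3	adhesion
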