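gene	contig	start	end
TP53	chr1	1000000	1100000
MUC16	chr1	3000000	3100000
DGKZ	chr1	5000000	5100000
EGFR	chr1	7000000	7100000
BRCA2	chr1	9000000	9100000
APC	chr1	11000000	11100000
FAT2	chr1	13000000	13100000
PIK3CA	chr1	15000000	15100000
SOX2	chr1	17000000	17100000
BCL6	chr1	19000000	19100000
CCND1	chr2	1000000	1100000
CTTN	chr2	3000000	3100000
CDKN2A	chr2	5000000	5100000
CDKN2B	chr2	7000000	7100000
MYC	chr2	9000000	9100000
FGFR1	chr2	11000000	11100000
NOTCH1	chr2	13000000	13100000
NOTCH2	chr2	15000000	15100000
NOTCH3	chr2	17000000	17100000
KRAS	chr2	19000000	19100000
PTEN	chr3	1000000	1100000
RB1	chr3	3000000	3100000
SMAD4	chr3	5000000	5100000
ARID1A	chr3	7000000	7100000
KMT2D	chr3	9000000	9100000
NFE2L2	chr3	11000000	11100000
ZNF750	chr3	13000000	13100000
CREBBP	chr3	15000000	15100000
EP300	chr3	17000000	17100000
ERBB2	chr3	19000000	19100000
HLA-A	chr4	1000000	1100000
HLA-B	chr4	3000000	3100000
TAP1	chr4	5000000	5100000
TAP2	chr4	7000000	7100000
B2M	chr4	9000000	9100000
TLR4	chr4	11000000	11100000
IL7R	chr4	13000000	13100000
JAK1	chr4	15000000	15100000
STAT1	chr4	17000000	17100000
IRF1	chr4	19000000	19100000
CD8A	chr5	1000000	1100000
NLRP3	chr5	3000000	3100000
TNF	chr5	5000000	5100000
IFNGR1	chr5	7000000	7100000
MYD88	chr5	9000000	9100000
CDK4	chr5	11000000	11100000
CDK6	chr5	13000000	13100000
CCNE1	chr5	15000000	15100000
CDC25A	chr5	17000000	17100000
E2F1	chr5	19000000	19100000
WEE1	chr6	1000000	1100000
MTOR	chr6	3000000	3100000
AKT1	chr6	5000000	5100000
MAPK1	chr6	7000000	7100000
RAF1	chr6	9000000	9100000
GRB2	chr6	11000000	11100000
IGF1R	chr6	13000000	13100000
BRCA1	chr6	15000000	15100000
ATM	chr6	17000000	17100000
ATR	chr6	19000000	19100000
MLH1	chr7	1000000	1100000
MSH2	chr7	3000000	3100000
RAD51	chr7	5000000	5100000
XRCC1	chr7	7000000	7100000
CDH1	chr7	9000000	9100000
CTNNB1	chr7	11000000	11100000
ITGB1	chr7	13000000	13100000
LAMA3	chr7	15000000	15100000
COL17A1	chr7	17000000	17100000
DSG3	chr7	19000000	19100000
CSMD1	chr8	5000000	5100000
PCDH15	chr8	18000000	18100000
WWOX	chr8	31000000	31100000
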