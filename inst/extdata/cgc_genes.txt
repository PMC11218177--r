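TP53
BRCA1
BRCA2
APC
CDKN2A
EGFR
PIK3CA
KRAS
PTEN
RB1
SMAD4
ARID1A
CREBBP
EP300
ERBB2
NOTCH1
CDH1
ATM
MLH1
MSH2
CCND1
MYC
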