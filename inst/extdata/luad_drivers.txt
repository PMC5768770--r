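# Example lung adenocarcinoma driver-gene catalog (editable; curated from
# commonly reported significantly mutated LUAD genes, not a frozen
# historical list).
EGFR
TP53
KRAS
STK11
KEAP1
NF1
BRAF
PIK3CA
RBM10
MET
RB1
CDKN2A
SETD2
ARID1A
SMARCA4
ATM
CTNNB1
LRP1B
MED12
AKT1
ERBB2
MGA
U2AF1
RIT1
SOX2
PTEN
NKX2-1
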