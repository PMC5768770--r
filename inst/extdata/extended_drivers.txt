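# Example pan-cancer extension of the driver catalog (editable; superset of
# the LUAD list once unioned on read).
VHL
PBRM1
BAP1
KDM5C
MTOR
APC
FBXW7
NRAS
IDH1
IDH2
CDH1
GATA3
MAP2K1
MAP3K1
NOTCH1
FGFR3
ERBB3
CREBBP
EP300
ARID2
KMT2C
KMT2D
SPOP
SF3B1
DNMT3A
TET2
MDM2
MDM4
MYC
MCL1
TERT
HGF
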