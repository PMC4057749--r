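id,degree
DRD2,17
OPRM,17
ADRB2,13
AA2AR,12
AA1R,11
OPRK,10
OPRD,10
GHSR,10
5HT1A,10
S1PR3,9
S1PR1,9
CNR1,9
SCTR,8
P2RY1,8
LPAR1,8
AGTR1,8
SSR5,7
P2RY2,7
LPAR3,7
LPAR2,7
GRM2,7
GPR4,7
DRD1,7
S1PR2,6
P2Y12,6
OGR1,6
GRM5,6
CXCR4,6
CCR5,6
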