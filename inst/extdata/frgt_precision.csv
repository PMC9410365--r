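id,precision_without_augmentation,precision_with_augmentation
DR,99.83,99.91
PD,99.40,99.81
CC,99.22,99.89
AC,99.90,100
CL,99.83,100
CT,98.25,99.47
MK,98.81,99.78
AN,83.87,95.87
HF,98.77,100
NS,99.01,100
AV,97.06,100
CV,97.56,99.32
PM,100,100
ZS,96,98.75
HM,90.91,97.62
LF,100,100
SB,100,100
S,94.12,100
PV,92.86,100
ZC,92.31,100
NN,66.67,81.25
BU,93.33,100
SF,96,96
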