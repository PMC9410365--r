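id,species,samples
DR,Dascyllus reticulatus,12112
PD,Plectroglyphidodon dickii,2683
CC,Chromis chrysura,3593
AC,Amphiprion clarkia,4049
CL,Chaetodon lunulatus,2534
CT,Chaetodon trifascialis,190
MK,Myripristis kuntee,450
AN,Acanthurus nigrofuscus,218
HF,Hemigymnus fasciatus,241
NS,Neoniphon samara,299
AV,Abudefduf vaigiensis,98
CV,Canthigaster valentine,147
PM,Pomacentrus moluccensis,181
ZS,Zebrasoma scopas,90
HM,Hemigymnus melapterus,42
LF,Lutjanus fulvus,206
SB,Scolopsis bilineata,49
S,Scaridae,56
PV,Pempheris vanicolensis,29
ZC,Zanclus cornutus,21
NN,Neoglyphidodon nigroris,16
BU,Balistapus undulates,41
SF,Siganus fuscescens,25
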