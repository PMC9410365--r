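id,species,family,train,validation,test
AN,Acanthurus nigrofuscus,Acanthuridae,2244,561,129
ZS,Zebrasoma scopas,Acanthuridae,274,69,187
CL,Chaetodon lunulatus,Chaetodontidae,2969,742,1876
CS,Chaetodon speculum,Chaetodontidae,130,32,0
CT,Chaetodon trifascialis,Chaetodontidae,545,136,1319
MK,Myripristis kuntee,Holocentridae,2597,649,118
HM,Hemigymnus melapterus,Labridae,285,71,0
PV,Pempheris Vanicolensis,Pempheridae,838,210,0
AC,Amphiprion clarkia,Pomacentridae,2677,669,553
AV,Abudefduf vaigiensis,Pomacentridae,349,87,94
CC,Chromis chrysura,Pomacentridae,3086,772,24
DA,Dascyllus aruanus,Pomacentridae,1422,355,2013
DR,Dascyllus reticulatus,Pomacentridae,5066,1267,4898
NN,Neoglyphidodon nigroris,Pomacentridae,171,43,1643
PD,Plectrogly-Phidodon dickii,Pomacentridae,2355,589,676
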