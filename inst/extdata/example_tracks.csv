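scorer,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm,spinalmcm
bodyparts,vessel01,vessel01,vessel01,vessel02,vessel02,vessel02,vessel03,vessel03,vessel03,vessel04,vessel04,vessel04
coords,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood
0,51.6778041773037,6.97992631148282,0.997929001525044,53.6334008034791,28.7862953859026,0.999509550577495,50.3291511388048,66.1552825383465,0.997100176778622,0,0,0
1,51.8914245994683,6.94331108622528,0.995044728978537,53.1291435687078,29.2128901493608,0.995293109936174,21.8658556747425,48.2370814764077,0.723608000040986,0,0,0
2,52.3133614777058,11.4891084844369,0.996468698059907,53.355871344107,32.9184011353552,0.995228504745755,50.2230481428199,69.8353415375343,0.995503423409536,0,0,0
3,52.2894261460605,11.9698562000148,0.996386874789605,53.3638746746764,34.3495613365231,0.999944042545976,50.5322571678744,71.0223500409842,0.998034184222342,0,0,0
4,52.04737440296,11.301179581581,0.999067871074658,53.4726934860546,33.0659317116626,0.996029124800116,50.2830542155236,70.1885680385788,0.996062158121495,0,0,0
5,51.9371973941249,12.0617290642809,0.996302138856845,53.5757449249882,33.7577399989136,0.999645279860124,50.4755217282125,70.9771218480995,0.999473703755066,0,0,0
6,52.0106649710274,6.18420244028751,0.998622029463295,53.8828001663671,27.9861519475632,0.995971517760772,50.3155386391078,65.1266888141691,0.997815990168601,0,0,0
7,51.9250260801413,1.42802845048349,0.999530460756505,53.3692682379204,23.6625036038042,0.995634004683234,50.2672663050524,60.4618126290985,0.996238623920362,0,0,0
8,0,0,0,53.3781185301005,17.4668835757693,0.997696844055317,-8.93971293644976,83.5246913020979,0.283232696773484,43.9138540952271,92.1752499626761,0.999207328358898
9,0,0,0,14.4320676419724,-16.9538650793359,0.305604211287573,50.3475378990331,53.8404580626386,0.996331661584554,43.575218002661,91.7144216032204,0.997074046141934
10,0,0,0,28.3099149599264,28.1128145935473,0.72646458032541,49.9933266946184,53.8977945056942,0.998771286107367,44.0463158186148,92.2137869744897,0.998820154422428
11,0,0,0,53.7583996114618,16.9215009423337,0.995420524283545,50.6497187450782,54.3616360743184,0.999789716398809,44.0133623077572,91.7093657180141,0.995047387909144
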