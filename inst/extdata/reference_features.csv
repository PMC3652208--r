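RRn,RRnPrime,QRSn,PRn,QTn,STn,Rn,Pn,Tn
0.8477,0.8692,0.0742,0.1663,0.2930,0.2188,1.8149,0.0570,0.6817
0.9023,0.8931,0.0742,0.1445,0.2891,0.2148,1.6339,0.0142,0.5926
0.8594,0.8916,0.0781,0.1406,0.2852,0.2070,2.3085,0.0579,0.6125
0.8281,0.8034,0.0742,0.1663,0.2931,0.2109,2.1007,0.0469,0.6247
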