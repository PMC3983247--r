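"factor","level1","level2","level3"
"SM0",0.005,0.007,0.01
"SM1",0.011,0.013,0.017
"SM2",0.5,0.81,1
"SM3",0.6,0.9,1
"DV0",10,14,18
"DV1",15,20,26
"DV2",30,39,45
"DV3",40,46,50
"TTCS",2,4,5
"THCS",-0.05,-0.01,0
"TTHS",40,46,50
"THHS",0.7,0.9,1
"SMWS",0.6,0.9,1
"HWS",0.018,0.022,0.029
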