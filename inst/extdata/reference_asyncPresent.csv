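"model","simpleStates","complexStates","complexEdges"
"CD-V1","0000000,0001000,1000000,1001000",0,0
"CD-V2","0000000,0001110,1000000",32,84
"CD-V3","0000000,0001100,1000000,1001100",0,0
"CD-V4","0000000,0001000,1000000,1001000",0,0
"CD-V5","0000000,0001110,1000000",32,84
"CD-V6","0000000,0001100,1000000,1001100",0,0
"CD-V7","0000000,0001110,1000000",32,84
"CD-V8","0000000,0001110,1000000",32,84
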