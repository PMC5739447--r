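"state","CD-V1","CD-V2","CD-V3","CD-V4","CD-V5","CD-V6","CD-V7","CD-V8","CD-PBN"
"0000000",0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125
"0001000",0.125,NA,NA,0.125,NA,NA,NA,NA,0.064
"0001010",NA,NA,NA,NA,NA,NA,NA,NA,0.016
"0001100",NA,NA,0.125,NA,NA,0.125,NA,NA,0.036
"0001110",NA,0.125,NA,NA,0.125,NA,0.125,0.125,0.009
"1000000",0.219,0.219,0.219,0.172,0.172,0.172,0.219,0.172,0.177
"1001000",0.531,0.047,NA,0.578,0.047,NA,0.047,0.047,0.301
"1001010",NA,0.047,NA,NA,0.063,NA,NA,NA,0.057
"1001100",NA,NA,0.531,NA,NA,0.578,NA,NA,0.057
"1001101",NA,NA,NA,NA,NA,NA,NA,NA,0.057
"1001110",NA,NA,NA,NA,NA,NA,0.047,0.063,0.014
"1001111",NA,0.203,NA,NA,0.234,NA,0.203,0.234,0.014
"1111001",NA,NA,NA,NA,NA,NA,NA,NA,0.002
"1111011",NA,NA,NA,NA,NA,NA,NA,NA,0.009
"1111101",NA,0.234,NA,NA,0.234,NA,0.234,0.234,0.012
"1111111",NA,NA,NA,NA,NA,NA,NA,NA,0.048
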