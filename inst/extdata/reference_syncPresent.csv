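"model","states","basinPct"
"CD-V1","0000000",12.5
"CD-V1","0001000",12.5
"CD-V1","1000000",21.88
"CD-V1","1001000",53.12
"CD-V2","0000000",12.5
"CD-V2","0001110",12.5
"CD-V2","1000000",21.88
"CD-V2","1001000 > 1001010 > 1001111 > 1111101",53.12
"CD-V3","0000000",12.5
"CD-V3","0001100",12.5
"CD-V3","1000000",21.88
"CD-V3","1001100",53.12
"CD-V4","0000000",12.5
"CD-V4","0001000",12.5
"CD-V4","1000000",17.19
"CD-V4","1001000",57.81
"CD-V5","0000000",12.5
"CD-V5","0001110",12.5
"CD-V5","1000000",17.19
"CD-V5","1001000 > 1001010 > 1001111 > 1111101",57.81
"CD-V6","0000000",12.5
"CD-V6","0001100",12.5
"CD-V6","1000000",17.19
"CD-V6","1001100",57.81
"CD-V7","0000000",12.5
"CD-V7","0001110",12.5
"CD-V7","1000000",21.88
"CD-V7","1001000 > 1001110 > 1001111 > 1111101",53.12
"CD-V8","0000000",12.5
"CD-V8","0001110",12.5
"CD-V8","1000000",17.19
"CD-V8","1001000 > 1001110 > 1001111 > 1111101",57.81
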