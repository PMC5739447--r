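"model","states","basinPct"
"CD1965-V1","0000",12.5
"CD1965-V1","0001",12.5
"CD1965-V1","0100",12.5
"CD1965-V1","0111",12.5
"CD1965-V1","1000",6.25
"CD1965-V1","1001",18.75
"CD1965-V1","1100",6.25
"CD1965-V1","1111",18.75
"CD1965-V2","0000",12.5
"CD1965-V2","0001",12.5
"CD1965-V2","0101",12.5
"CD1965-V2","0110",12.5
"CD1965-V2","1000",6.25
"CD1965-V2","1001",18.75
"CD1965-V2","1101",25
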