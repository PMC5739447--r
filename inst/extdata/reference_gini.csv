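"model","gini"
"CD1965-V1",0.575
"CD1965-V2",0.575
"CD-V1",0.918
"CD-V2",0.908
"CD-V3",0.904
"CD-V4",0.918
"CD-V5",0.908
"CD-V6",0.904
"CD-V7",0.921
"CD-V8",0.921
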