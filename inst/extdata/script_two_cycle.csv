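sagittal,load,load_contra,expected
0.3,0.5,0,ES
0.3,0.9,0,ES
-0.1,0.9,0,LS
-0.1,0.9,0,LS
-0.3,0.8,0,LO
-0.3,0.5,0,LO
-0.3,0.05,0.5,SW
0,0,0.5,SW
0.2,0,0.5,LN
0.25,0.1,0.5,LN
0.3,0.5,0,ES
0.3,0.9,0,ES
-0.1,0.9,0,LS
-0.1,0.9,0,LS
-0.3,0.8,0,LO
-0.3,0.5,0,LO
-0.3,0.05,0.5,SW
0,0,0.5,SW
0.2,0,0.5,LN
0.25,0.1,0.5,LN
0.25,0.5,0.5,ES
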