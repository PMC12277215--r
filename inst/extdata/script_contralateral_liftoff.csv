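sagittal,load,load_contra,expected
0.3,0.5,0,ES
-0.05,0.9,0,LS
-0.05,0.9,0.4,LO
-0.05,0.05,0.9,SW
0.2,0,0.9,LN
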