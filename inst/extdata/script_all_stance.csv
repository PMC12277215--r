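sagittal,load,load_contra,expected
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
0.3,0.9,0,ES
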