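x,y,z
0.0421,-0.0137,0.0562
-0.0298,0.0455,0.0611
0.0117,0.0522,0.0489
-0.0504,-0.0211,0.0533
0.0366,0.0408,0.0702
-0.0092,-0.0561,0.0644
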