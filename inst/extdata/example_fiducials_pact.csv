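"x","y","z"
0.048028,-0.006648,0.0577
-0.034609,0.03631,0.0626
0.004591,0.051492,0.0504
-0.040912,-0.033118,0.0548
0.031317,0.045518,0.0717
0.006665,-0.058787,0.0659
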