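"step","C0_in","C1_in"
1,0.01,0.01
2,0.12,0.12
3,0.23,0.23
4,0.34,0.34
5,0.45,0.45
6,0.56,0.56
7,0.67,0.67
8,0.78,0.78
9,0.89,0.89
10,1,1
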