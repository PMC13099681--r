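item,a,c
1,0.68,1.60
2,1.27,2.24
3,1.56,2.39
4,1.22,1.57
5,1.38,1.14
6,1.80,0.21
7,1.33,-0.16
8,2.02,-1.19
9,1.16,-1.23
10,1.11,-1.70
11,0.94,-1.66
12,0.80,-1.83
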