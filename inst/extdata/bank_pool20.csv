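item,a,c
1,0.66,-0.18
2,0.76,0.14
3,0.89,-0.05
4,0.89,0.80
5,0.97,1.22
6,1.04,-0.74
7,1.18,-0.70
8,1.24,-0.08
9,1.26,0.09
10,1.30,0.00
11,1.30,-2.07
12,1.30,1.26
13,1.37,0.90
14,1.44,-1.08
15,1.47,0.09
16,1.81,0.34
17,1.83,-2.20
18,2.07,0.64
19,2.36,-0.21
20,3.19,-2.49
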