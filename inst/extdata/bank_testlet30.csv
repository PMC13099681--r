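item,a,c,testlet
1,2.49,-0.16,1
2,1.26,0.14,1
3,2.15,0.21,1
4,2.17,0.16,1
5,2.45,0.78,1
6,0.65,-0.13,1
7,1.13,0.55,1
8,2.34,0.30,1
9,1.85,-1.12,1
10,1.07,-0.92,1
11,1.28,0.57,2
12,0.96,0.48,2
13,0.83,1.08,2
14,0.81,-2.23,2
15,2.45,0.61,2
16,1.35,-2.41,2
17,0.63,-0.06,2
18,1.48,-2.48,2
19,1.08,1.35,2
20,0.92,-0.86,2
21,0.91,2.17,3
22,1.66,0.21,3
23,1.68,0.84,3
24,2.28,0.57,3
25,0.72,1.80,3
26,1.49,-0.03,3
27,1.08,-1.14,3
28,1.47,-1.19,3
29,2.40,-0.92,3
30,2.35,0.05,3
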