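item,a,b,c
1,0.64,-1.67,1.06
2,1.43,-2.33,3.34
3,0.89,-2.61,2.32
4,1.16,-2.26,2.62
5,1.46,0.90,-1.32
6,0.96,0.90,-0.86
7,0.54,0.81,-0.44
8,0.50,-0.62,0.31
9,1.11,2.87,-3.19
10,0.80,1.87,-1.50
11,1.17,2.98,-3.48
12,0.97,1.68,-1.63
13,2.42,-1.58,3.82
14,1.78,-2.22,3.95
15,1.65,-2.98,4.93
16,1.82,-1.51,2.76
17,2.01,1.13,-2.27
18,1.57,-0.65,1.01
19,1.97,0.79,-1.55
20,2.42,-0.32,0.78
21,2.43,2.25,-5.46
22,2.30,2.84,-6.55
23,1.98,2.77,-5.49
24,1.78,2.01,-3.57
25,2.61,-2.22,5.77
26,3.15,-1.65,5.20
27,2.60,-2.53,6.59
28,2.58,-1.59,4.11
29,3.46,-0.93,3.20
30,3.45,-0.17,0.58
31,2.76,0.51,-1.41
32,2.88,1.46,-4.19
33,3.17,2.99,-9.46
34,3.47,1.77,-6.16
35,2.94,2.51,-7.38
36,3.15,2.07,-6.54
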