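item,a,b,c
1,0.64,-1.67,1.06
2,1.43,-2.33,3.34
3,0.89,-2.61,2.32
4,1.16,-2.26,2.62
5,1.46,-1.80,2.63
6,0.96,-1.80,1.72
7,0.54,0.81,-0.44
8,0.50,-0.62,0.31
9,1.11,1.24,-1.38
10,0.80,-0.75,0.60
11,1.17,1.46,-1.71
12,0.97,-1.13,1.09
13,1.42,2.92,-4.13
14,0.78,2.28,-1.77
15,0.65,1.52,-1.00
16,0.82,2.99,-2.46
17,1.01,2.81,-2.85
18,0.57,1.93,-1.09
19,1.97,-1.86,3.66
20,2.42,-2.41,5.84
21,2.43,-2.25,5.47
22,2.30,-1.66,3.81
23,1.98,-1.73,3.43
24,1.78,-2.49,4.42
25,1.61,0.07,-0.11
26,2.15,1.20,-2.58
27,1.60,-0.56,0.91
28,1.58,1.31,-2.07
29,2.46,-0.93,2.28
30,2.45,-0.17,0.41
31,1.76,2.50,-4.42
32,1.88,2.98,-5.59
33,2.17,2.99,-6.47
34,2.47,1.77,-4.38
35,1.94,2.51,-4.87
36,2.15,2.07,-4.47
37,3.17,-1.92,6.09
38,3.28,-2.52,8.27
39,2.60,-1.75,4.54
40,2.53,-2.64,6.67
41,3.36,-2.92,9.82
42,2.69,-2.29,6.16
43,2.74,-0.42,1.16
44,2.65,-1.09,2.89
45,2.60,-1.04,2.71
46,2.64,-1.41,3.73
47,3.23,0.53,-1.71
48,2.94,-1.13,3.31
49,2.68,2.41,-6.46
50,2.77,2.57,-7.12
51,2.87,1.92,-5.50
52,3.38,1.75,-5.92
53,2.60,2.96,-7.70
54,3.46,1.69,-5.83
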