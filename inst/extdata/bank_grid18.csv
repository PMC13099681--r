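item,a,b,c,level_a,level_b,level_c
1,0.64,-1.67,1.06,low,low,medium
2,1.43,-2.33,3.34,low,low,medium
3,0.89,-0.73,0.65,low,medium,medium
4,1.16,-0.02,0.03,low,medium,medium
5,1.46,2.70,-3.96,low,high,low
6,0.96,2.70,-2.58,low,high,medium
7,1.54,-1.85,2.85,medium,low,medium
8,1.50,-2.56,3.85,medium,low,high
9,2.11,1.24,-2.62,medium,medium,medium
10,1.80,-0.75,1.36,medium,medium,medium
11,2.17,2.98,-6.46,medium,high,low
12,1.97,1.68,-3.32,medium,high,medium
13,3.42,-1.58,5.40,high,low,high
14,2.78,-2.22,6.17,high,low,high
15,2.65,-1.46,3.87,high,medium,high
16,2.82,1.47,-4.16,high,medium,low
17,3.01,2.81,-8.48,high,high,low
18,2.57,1.93,-4.95,high,high,low
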