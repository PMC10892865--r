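participant,mean,sd,median
1,2.27,0.69,2.31
2,1.42,0.74,1.24
3,1.95,0.76,1.84
4,2.14,0.57,2.17
5,1.08,0.65,1.00
6,1.78,0.64,1.66
7,1.84,0.92,1.59
8,2.11,0.60,2.00
9,1.93,0.75,1.71
10,1.39,0.70,1.32
11,1.71,0.61,1.65
12,1.96,0.75,1.73
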