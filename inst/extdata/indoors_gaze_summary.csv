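participant,mean,sd,median
1,2.01,1.21,1.80
2,2.18,0.97,2.03
3,1.63,0.80,1.49
4,1.68,1.03,1.33
5,1.02,0.71,0.78
6,1.75,0.73,1.54
7,1.66,0.80,1.47
8,1.58,1.10,1.19
9,1.50,0.65,1.24
10,1.59,0.70,1.60
11,1.71,0.71,1.53
12,1.68,1.05,1.34
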