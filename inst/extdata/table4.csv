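subject,session,interface,hint,state_1,state_2,state_3,state_4,state_5,state_6,state_7,state_8,state_9,state_10
4,1,static,N,0.67,0.29,,,0.04,,,,,
4,2,static,N,0.86,,,,0.14,,,,,
5,1,static,N,0.22,0.13,,,0.65,,,,,
5,2,static,N,0.31,0.42,0.04,,0.23,,,,,
9,1,static,N,,1,,,,,,,,
9,2,static,N,,1,,,,,,,,
11,1,static,N,0.25,0.75,,,,,,,,
11,2,static,N,0.91,0.09,,,,,,,,
15,1,static,Y,0.25,0.32,0.43,,,,,,,
15,2,static,Y,0.40,,0.60,,,,,,,
16,1,static,Y,,0.12,,0.88,,,,,,
16,2,static,Y,,0.05,,0.95,,,,,,
17,1,static,Y,,0.88,0.12,,,,,,,
17,2,static,Y,,,,1,,,,,,
19,1,static,Y,,0.04,0.96,,,,,,,
19,2,static,Y,,,1,,,,,,,
20,1,static,Y,,,1,,,,,,,
20,2,static,Y,,,0.30,0.70,,,,,,
1,1,wiggle,N,,,,,,,,1,,
1,2,wiggle,N,,,,,,,,1,,
2,1,wiggle,Y,,,,,,,,1,,
2,2,wiggle,Y,,,,,,,,1,,
3,1,wiggle,Y,,,,,0.01,,,0.95,0.04,
3,2,wiggle,Y,0.03,,,,0.01,,0.22,,,0.74
6,1,wiggle,N,,0.09,,,0.17,,0.01,0.69,0.04,
6,2,wiggle,N,0.17,,,,0.39,,0.16,0.05,0.23,
7,1,wiggle,N,,,,,0.01,,0.09,0.81,0.09,
7,2,wiggle,N,,0.02,,,0.31,,0.04,0.56,0.08,
8,1,wiggle,Y,,,,,,0.65,,0.35,,
8,2,wiggle,Y,,,,,,1,,,,
10,1,wiggle,Y,,,,,,,,0.66,,0.34
10,2,wiggle,Y,,,,,,,,0.07,,0.93
12,1,wiggle,Y,,,,,,,,1,,
12,2,wiggle,Y,,,,,,,,1,,
13,1,wiggle,N,,,,,,,,0.14,0.86,
13,2,wiggle,N,,,,,,,0.07,,0.93,
14,1,wiggle,Y,,,,,0.08,,0.15,0.11,0.66,
14,2,wiggle,Y,,,,,0.01,,0.01,0.50,0.48,
18,1,wiggle,N,,,,,0.01,,0.37,,0.10,0.52
18,2,wiggle,N,,,,,0.11,,0.82,,0.07,
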