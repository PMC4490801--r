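state,kurtosis,max_average
1,1.714,0.047
2,-5.652,0.032
3,-4.657,0.033
4,-5.568,0.030
5,3.973,0.055
6,-1.402,0.023
7,-4.393,0.036
8,3.104,0.043
9,1.714,0.044
10,2.771,0.048
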