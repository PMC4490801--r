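subject,interface,hint,rule_description,correct
1,wiggle,N,,
2,wiggle,Y,By grouping blocks with similar colors,No
3,wiggle,Y,At first I thought I was making the colors move but in the end i was convinced that it was automatic yet I still sought for the rule of the game,No
4,static,N,,
5,static,N,Don't think too much...,No
6,wiggle,N,Touching the different squares,No
7,wiggle,N,,
8,wiggle,N,,
9,static,N,,
10,wiggle,Y,Don't know the exact rule,No
11,static,N,There is no rule,No
12,wiggle,N,,
13,wiggle,N,The more of the same colors the higher the score,No
14,wiggle,N,To put colored squares into groups and cluster them,No
15,static,Y,Turn three squares of the same color into four squares by annexing a fourth neighboring square of a different color,Yes
16,static,N,Still matching 3 or more of the same color,Yes
17,static,Y,Three matching colored blocks needed to line up in any direction,Yes
18,wiggle,N,Gain more points by moving methodically across the screen/row,No
19,static,Y,Points are acquired by moving colored blocks one space at a time to construct groups of 3 or more boxes of the same color,Yes
20,static,Y,Move one block to make sure 3 adjacent blocks of the same color are touching,Yes
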