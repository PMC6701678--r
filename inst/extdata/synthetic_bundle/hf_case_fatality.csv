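year,death_prob,se
1,0.20000000000000001,0.020000000000000004
2,0.12,0.012
3,0.10000000000000001,0.010000000000000002
4,0.089999999999999997,0.0089999999999999993
5,0.089999999999999997,0.0089999999999999993
6,0.080000000000000002,0.0080000000000000002
7,0.080000000000000002,0.0080000000000000002
8,0.080000000000000002,0.0080000000000000002
9,0.080000000000000002,0.0080000000000000002
10,0.080000000000000002,0.0080000000000000002
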