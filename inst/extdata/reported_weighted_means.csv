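scenario_id,weighted_mean
0,55.36
1,47.86
2,49.83
3,33.26
4,50.26
5,40.87
6,44.79
7,23.02
8,34.10
9,15.83
10,18.48
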