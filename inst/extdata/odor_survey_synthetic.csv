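respondent,site,odor_type,detection_distance,walk_start
1,synthetic,manure,66,150
2,synthetic,manure,83,150
3,synthetic,manure,62,150
4,synthetic,manure,27,150
5,synthetic,manure,53,150
6,synthetic,manure,78,150
7,synthetic,manure,15,150
8,synthetic,manure,40,150
9,synthetic,manure,85,150
10,synthetic,manure,60,150
11,synthetic,manure,58,150
12,synthetic,manure,48,150
13,synthetic,manure,70,150
14,synthetic,manure,39,150
15,synthetic,manure,69,150
16,synthetic,manure,70,150
17,synthetic,manure,84,150
18,synthetic,manure,65,150
19,synthetic,manure,33,150
20,synthetic,manure,44,150
21,synthetic,manure,47,150
22,synthetic,manure,81,150
23,synthetic,manure,84,150
24,synthetic,manure,38,150
25,synthetic,manure,34,150
26,synthetic,manure,62,150
27,synthetic,manure,61,150
28,synthetic,manure,64,150
29,synthetic,manure,56,150
30,synthetic,manure,72,150
31,synthetic,manure,75,150
32,synthetic,manure,61,150
33,synthetic,manure,107,150
34,synthetic,manure,59,150
35,synthetic,manure,28,150
36,synthetic,manure,44,150
37,synthetic,manure,44,150
38,synthetic,manure,76,150
39,synthetic,manure,58,150
40,synthetic,manure,61,150
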