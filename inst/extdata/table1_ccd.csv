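run,y1_coded,y2_coded,y3_coded,y4_coded,actual_pct,paper_predicted_pct
1,-1,-1,-1,-1,83.21,82.89
2,-1,-1,-1,1,80.37,80.26
3,-1,-1,1,-1,76.53,77.35
4,-1,-1,1,1,74.82,76.15
5,-1,1,-1,-1,80.15,81.83
6,-1,1,-1,1,76.38,76.28
7,-1,1,1,-1,73.75,73.66
8,-1,1,1,1,69.85,69.88
9,1,-1,-1,-1,87.82,87.35
10,1,-1,-1,1,85.38,82.54
11,1,-1,1,-1,83.34,83.23
12,1,-1,1,1,80.52,79.97
13,1,1,-1,-1,85.50,85.62
14,1,1,-1,1,82.99,81.63
15,1,1,1,-1,80.33,80.85
16,1,1,1,1,76.51,76.74
17,-2,0,0,0,76.29,75.87
18,2,0,0,0,78.52,80.11
19,0,-2,0,0,82.59,84.84
20,0,2,0,0,78.38,79.83
21,0,0,-2,0,78.43,81.47
22,0,0,2,0,71.87,71.38
23,0,0,0,-2,80.26,79.69
24,0,0,0,2,76.37,76.19
25,0,0,0,0,82.98,83.16
26,0,0,0,0,83.25,83.16
27,0,0,0,0,83.06,83.16
28,0,0,0,0,83.32,83.16
29,0,0,0,0,82.65,83.16
30,0,0,0,0,83.29,83.16
31,0,0,0,0,83.37,83.16
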