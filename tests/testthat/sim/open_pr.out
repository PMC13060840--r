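# pair distance distribution P(r)
# dr= 0.5
# dmax= 108.09768539479364
# normalized= TRUE
# self_term= 1152
# total_weight= 35712
0.25 0
0.75 0
1.25 0
1.75 0
2.25 0
2.75 0
3.25 0
3.75 0.125
4.25 0
4.75 0
5.25 0
5.75 0
6.25 0
6.75 0.044354838709677422
7.25 0.076612903225806453
7.75 0
8.25 0
8.75 0
9.25 0
9.75 0
10.25 0
10.75 0.11693548387096774
11.25 0
11.75 0
12.25 0
12.75 0
13.25 0
13.75 0.036290322580645164
14.25 0.076612903225806453
14.75 0
15.25 0
15.75 0
16.25 0
16.75 0
17.25 0.0080645161290322578
17.75 0.10080645161290322
18.25 0
18.75 0
19.25 0
19.75 0
20.25 0
20.75 0.024193548387096774
21.25 0.080645161290322578
21.75 0
22.25 0
22.75 0
23.25 0
23.75 0
24.25 0.024193548387096774
24.75 0.076612903225806453
25.25 0
25.75 0
26.25 0
26.75 0
27.25 0
27.75 0.052419354838709679
28.25 0.044354838709677422
28.75 0
29.25 0
29.75 0
30.25 0
30.75 0
31.25 0.032258064516129031
31.75 0.060483870967741937
32.25 0
32.75 0
33.25 0
33.75 0
34.25 0
34.75 0.048387096774193547
35.25 0.040322580645161289
35.75 0
36.25 0
36.75 0
37.25 0
37.75 0
38.25 0.040322580645161289
38.75 0.044354838709677422
39.25 0
39.75 0
40.25 0
40.75 0
41.25 0
41.75 0.044354838709677422
42.25 0.036290322580645164
42.75 0
43.25 0
43.75 0
44.25 0
44.75 0
45.25 0.048387096774193547
45.75 0.028225806451612902
46.25 0
46.75 0
47.25 0
47.75 0
48.25 0
48.75 0.052419354838709679
49.25 0.020161290322580645
49.75 0
50.25 0
50.75 0
51.25 0
51.75 0
52.25 0.056451612903225805
52.75 0.012096774193548387
53.25 0
53.75 0
54.25 0
54.75 0
55.25 0
55.75 0.064516129032258063
56.25 0
56.75 0
57.25 0
57.75 0
58.25 0
58.75 0
59.25 0.060483870967741937
59.75 0
60.25 0
60.75 0
61.25 0
61.75 0
62.25 0
62.75 0.056451612903225805
63.25 0
63.75 0
64.25 0
64.75 0
65.25 0
65.75 0
66.25 0.052419354838709679
66.75 0
67.25 0
67.75 0
68.25 0
68.75 0
69.25 0
69.75 0.048387096774193547
70.25 0
70.75 0
71.25 0
71.75 0
72.25 0
72.75 0
73.25 0.044354838709677422
73.75 0
74.25 0
74.75 0
75.25 0
75.75 0
76.25 0
76.75 0.040322580645161289
77.25 0
77.75 0
78.25 0
78.75 0
79.25 0
79.75 0
80.25 0.036290322580645164
80.75 0
81.25 0
81.75 0
82.25 0
82.75 0
83.25 0
83.75 0.032258064516129031
84.25 0
84.75 0
85.25 0
85.75 0
86.25 0
86.75 0
87.25 0.028225806451612902
87.75 0
88.25 0
88.75 0
89.25 0
89.75 0
90.25 0
90.75 0.024193548387096774
91.25 0
91.75 0
92.25 0
92.75 0
93.25 0
93.75 0
94.25 0.020161290322580645
94.75 0
95.25 0
95.75 0
96.25 0
96.75 0
97.25 0
97.75 0.016129032258064516
98.25 0
98.75 0
99.25 0
99.75 0
100.25 0
100.75 0
101.25 0.012096774193548387
101.75 0
102.25 0
102.75 0
103.25 0
103.75 0
104.25 0
104.75 0.0080645161290322578
105.25 0
105.75 0
106.25 0
106.75 0
107.25 0
107.75 0
108.25 0.0040322580645161289
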