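# pair distance distribution P(r)
# dr= 0.5
# dmax= 62.316623442265133
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
4.25 0.0040322580645161289
4.75 0
5.25 0
5.75 0
6.25 0
6.75 0.040322580645161289
7.25 0.084677419354838704
7.75 0
8.25 0.0040322580645161289
8.75 0
9.25 0
9.75 0.0080645161290322578
10.25 0
10.75 0.11693548387096774
11.25 0
11.75 0
12.25 0.0040322580645161289
12.75 0
13.25 0.016129032258064516
13.75 0.0080645161290322578
14.25 0.10080645161290322
14.75 0
15.25 0
15.75 0
16.25 0.0040322580645161289
16.75 0.016129032258064516
17.25 0.0080645161290322578
17.75 0.092741935483870969
18.25 0.0080645161290322578
18.75 0
19.25 0
19.75 0.0080645161290322578
20.25 0.020161290322580645
20.75 0.0080645161290322578
21.25 0.084677419354838704
21.75 0
22.25 0.0080645161290322578
22.75 0
23.25 0.016129032258064516
23.75 0.016129032258064516
24.25 0.0040322580645161289
24.75 0.084677419354838704
25.25 0
25.75 0
26.25 0.024193548387096774
26.75 0.0080645161290322578
27.25 0.0080645161290322578
27.75 0.016129032258064516
28.25 0.064516129032258063
28.75 0.0080645161290322578
29.25 0
29.75 0.024193548387096774
30.25 0.024193548387096774
30.75 0
31.25 0.0080645161290322578
31.75 0.060483870967741937
32.25 0.0040322580645161289
32.75 0.024193548387096774
33.25 0.016129032258064516
33.75 0.0080645161290322578
34.25 0.016129032258064516
34.75 0
35.25 0.060483870967741937
35.75 0
36.25 0.028225806451612902
36.75 0.016129032258064516
37.25 0.016129032258064516
37.75 0.0080645161290322578
38.25 0.0080645161290322578
38.75 0.044354838709677422
39.25 0.016129032258064516
39.75 0.016129032258064516
40.25 0.020161290322580645
40.75 0.024193548387096774
41.25 0
41.75 0.0080645161290322578
42.25 0.044354838709677422
42.75 0.016129032258064516
43.25 0.024193548387096774
43.75 0.016129032258064516
44.25 0.012096774193548387
44.75 0.016129032258064516
45.25 0
45.75 0.036290322580645164
46.25 0.040322580645161289
46.75 0.016129032258064516
47.25 0.016129032258064516
47.75 0.0080645161290322578
48.25 0.012096774193548387
48.75 0.0080645161290322578
49.25 0.036290322580645164
49.75 0.032258064516129031
50.25 0.016129032258064516
50.75 0.016129032258064516
51.25 0.016129032258064516
51.75 0
52.25 0.012096774193548387
52.75 0.036290322580645164
53.25 0.016129032258064516
53.75 0
54.25 0.016129032258064516
54.75 0.016129032258064516
55.25 0
55.75 0
56.25 0.012096774193548387
56.75 0.0080645161290322578
57.25 0.0040322580645161289
57.75 0
58.25 0.0080645161290322578
58.75 0.0040322580645161289
59.25 0
59.75 0
60.25 0.0080645161290322578
60.75 0
61.25 0
61.75 0
62.25 0.0040322580645161289
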