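# pair distance distribution P(r)
# dr= 0.5
# dmax= 33.984987111958709
# normalized= TRUE
# self_term= 864
# total_weight= 19872
0.25 0
0.75 0
1.25 0
1.75 0
2.25 0
2.75 0.014492753623188406
3.25 0.021739130434782608
3.75 0.072463768115942032
4.25 0.086956521739130432
4.75 0.065217391304347824
5.25 0.065217391304347824
5.75 0.15942028985507245
6.25 0.09420289855072464
6.75 0.014492753623188406
7.25 0.028985507246376812
7.75 0.028985507246376812
8.25 0.028985507246376812
8.75 0.043478260869565216
9.25 0.079710144927536225
9.75 0.050724637681159424
10.25 0.072463768115942032
10.75 0.043478260869565216
11.25 0.036231884057971016
11.75 0.043478260869565216
12.25 0.036231884057971016
12.75 0.021739130434782608
13.25 0.021739130434782608
13.75 0.036231884057971016
14.25 0.072463768115942032
14.75 0.050724637681159424
15.25 0.028985507246376812
15.75 0.057971014492753624
16.25 0.007246376811594203
16.75 0.036231884057971016
17.25 0.028985507246376812
17.75 0.028985507246376812
18.25 0.014492753623188406
18.75 0.028985507246376812
19.25 0.036231884057971016
19.75 0.028985507246376812
20.25 0.014492753623188406
20.75 0.043478260869565216
21.25 0.021739130434782608
21.75 0.014492753623188406
22.25 0.014492753623188406
22.75 0.043478260869565216
23.25 0
23.75 0.014492753623188406
24.25 0.028985507246376812
24.75 0.021739130434782608
25.25 0.007246376811594203
25.75 0.007246376811594203
26.25 0.021739130434782608
26.75 0.028985507246376812
27.25 0.014492753623188406
27.75 0.007246376811594203
28.25 0.021739130434782608
28.75 0.014492753623188406
29.25 0.007246376811594203
29.75 0.007246376811594203
30.25 0.014492753623188406
30.75 0.007246376811594203
31.25 0
31.75 0.007246376811594203
32.25 0.014492753623188406
32.75 0
33.25 0.007246376811594203
33.75 0.007246376811594203
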