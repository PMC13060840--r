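# pair distance distribution P(r)
# dr= 0.5
# dmax= 33.626450184341486
# normalized= TRUE
# self_term= 864
# total_weight= 19872
0.25 0
0.75 0
1.25 0
1.75 0
2.25 0
2.75 0.007246376811594203
3.25 0.043478260869565216
3.75 0.079710144927536225
4.25 0.043478260869565216
4.75 0.10144927536231885
5.25 0.12318840579710146
5.75 0.086956521739130432
6.25 0.050724637681159424
6.75 0.050724637681159424
7.25 0.043478260869565216
7.75 0.014492753623188406
8.25 0.050724637681159424
8.75 0.057971014492753624
9.25 0.072463768115942032
9.75 0.050724637681159424
10.25 0.028985507246376812
10.75 0.079710144927536225
11.25 0.028985507246376812
11.75 0.028985507246376812
12.25 0.028985507246376812
12.75 0.028985507246376812
13.25 0.050724637681159424
13.75 0.021739130434782608
14.25 0.050724637681159424
14.75 0.021739130434782608
15.25 0.043478260869565216
15.75 0.036231884057971016
16.25 0.028985507246376812
16.75 0.043478260869565216
17.25 0.021739130434782608
17.75 0.028985507246376812
18.25 0.021739130434782608
18.75 0.036231884057971016
19.25 0.007246376811594203
19.75 0.043478260869565216
20.25 0.036231884057971016
20.75 0.021739130434782608
21.25 0.028985507246376812
21.75 0.028985507246376812
22.25 0.014492753623188406
22.75 0.036231884057971016
23.25 0.014492753623188406
23.75 0.021739130434782608
24.25 0.021739130434782608
24.75 0.007246376811594203
25.25 0.036231884057971016
25.75 0.014492753623188406
26.25 0.014492753623188406
26.75 0.021739130434782608
27.25 0.014492753623188406
27.75 0.007246376811594203
28.25 0.007246376811594203
28.75 0.021739130434782608
29.25 0.007246376811594203
29.75 0.007246376811594203
30.25 0
30.75 0.014492753623188406
31.25 0.014492753623188406
31.75 0
32.25 0.007246376811594203
32.75 0.007246376811594203
33.25 0.007246376811594203
33.75 0.007246376811594203
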