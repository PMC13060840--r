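# q intensity sigma
0.0050000000000000001 35554.695551103687 1835.2187670638339
0.01 36562.686725727151 1811.5008345321303
0.014999999999999999 33972.955641282984 1772.7143225413829
0.02 37142.643806750762 1719.9426183462217
0.025000000000000001 33638.031068050521 1654.6407048126357
0.029999999999999999 30276.368028863257 1578.5770286377756
0.035000000000000003 30603.378185762125 1493.7637176166106
0.040000000000000001 29082.980443886954 1402.3784880122862
0.044999999999999998 26886.001772325908 1306.6819341062508
0.050000000000000003 23809.486488497609 1208.9340453391064
0.055 23906.338128424399 1111.3137466964106
0.059999999999999998 20712.920536506237 1015.8450114769823
0.065000000000000002 17912.420432098887 924.33266982575992
0.070000000000000007 14909.603099243895 838.31045889940651
0.074999999999999997 16033.889466862671 759.00316687388522
0.080000000000000002 13715.196045813178 687.30395464930064
0.085000000000000006 12465.243860589941 623.76714073554638
0.089999999999999997 11908.999356314403 568.61595156280737
0.095000000000000001 10863.763952539146 521.76401425948961
0.10000000000000001 9943.7393031526353 482.84873992805763
0.105 9440.1956960664756 451.27424387766473
0.11 8858.6162349210335 426.26109783571229
0.115 8168.3409117824767 406.90002092454711
0.12 7063.8950298518357 392.20659415293915
0.125 7859.7460057136277 381.17422047158232
0.13 7435.5305876178945 372.82283316555544
0.13500000000000001 7267.7663758221406 366.24125589301951
0.14000000000000001 6682.0470795324145 360.62160849564907
0.14499999999999999 6935.8146094156709 355.28470042516057
0.14999999999999999 7140.0709249515712 349.69592325945206
0.155 7336.1022090872493 343.47171094488687
0.16 6692.9675458027868 336.3771494261207
0.16500000000000001 6693.5938806086451 328.31575905968202
0.17000000000000001 6369.0758097916478 319.31282245813253
0.17500000000000002 5763.6859630055342 309.49387292482834
0.17999999999999999 5857.0934413366394 299.06008758930642
0.185 5651.5879597045669 288.26234532495909
0.19 5531.0603103299136 277.37562002592614
0.19500000000000001 5626.8534511943462 266.67519834670674
0.20000000000000001 5324.0095556596052 256.41595583253275
0.20500000000000002 4895.7053676411615 246.8156180366048
0.20999999999999999 4700.5410667946117 238.04259695516146
0.215 4764.6200226982382 230.20865120533963
0.22 4591.6656485148442 223.36629267784588
0.22500000000000001 4200.3997953108901 217.51057202074509
0.23000000000000001 4101.2901112311101 212.58463556696475
0.23500000000000001 4245.7764221759589 208.48826801699076
0.23999999999999999 4259.3877687945569 205.08852427254152
0.245 4021.9102827379506 202.23151135078135
0.25 4171.0932244670266 199.75440379452098
0.255 4028.5617792018006 197.49685597422274
0.26000000000000001 3786.6864820994592 195.31110155737267
0.26500000000000001 3927.2638729020896 193.07019143876221
0.27000000000000002 3598.1398718916635 190.67400269592241
0.27500000000000002 4030.5409486325825 188.05283868149215
0.28000000000000003 4070.0803399354654 185.16862107736873
0.28500000000000003 3573.4373536237526 182.01383718256341
0.28999999999999998 3385.6794533401717 178.60854076546298
0.29499999999999998 3599.6146671127476 174.99580608334793
0.29999999999999999 3401.595749953437 171.23609867148059
0.30499999999999999 3750.0543936140421 167.40105262511818
0.31 3264.924312879315 163.56713438397998
0.315 3306.4196290677573 159.8096317766325
0.32000000000000001 3128.3206691999167 156.19734032375266
0.32500000000000001 2942.2012734443861 152.78823370966208
0.33000000000000002 3020.7744873474944 149.62630961437753
0.33500000000000002 2669.9349740141679 146.73970339268536
0.34000000000000002 3094.0465253395291 144.1400674379891
0.34500000000000003 2858.197457959754 141.82312949643833
0.35000000000000003 3099.0719947154348 139.77027338001525
0.35499999999999998 2824.6156558386115 137.95093361910608
0.35999999999999999 2629.7274163391148 136.32556316767045
0.36499999999999999 2779.3341970783722 134.84892038304497
0.37 2544.7913251637947 133.47342685376702
0.375 2477.376753396607 132.15236884507556
0.38 2654.9886060151657 130.84274896916727
0.38500000000000001 2532.743066320591 129.50763747668626
0.39000000000000001 2562.5000243541785 128.11792045008843
0.39500000000000002 2542.4834092991491 126.65339142362092
0.40000000000000002 2428.3126586646413 125.10318019110183
0.40500000000000003 2399.1000988541582 123.46555497749723
0.41000000000000003 2418.485778308328 121.74716960453577
0.41500000000000004 2540.5625880357597 119.96185436611175
0.41999999999999998 2182.6038220717805 118.12906736363749
0.42499999999999999 2394.5020299692696 116.27213202138692
0.42999999999999999 2326.4227178394308 114.41638696630453
0.435 2371.4389604831099 112.58736742472553
0.44 2182.476127540644 110.80912408394897
0.44500000000000001 2222.4254260691605 109.10276749412066
0.45000000000000001 2178.4152971559956 107.48530510680915
0.45500000000000002 2061.8861044369087 105.96881547461733
0.46000000000000002 2217.4942623923157 104.55998135591524
0.46500000000000002 2185.0227864482813 103.25998168048187
0.47000000000000003 2112.7615622376147 102.0647225197657
0.47500000000000003 2179.5226296244987 100.96537012778177
0.47999999999999998 2054.8029415950755 99.949135313767329
0.48499999999999999 1853.6220187318613 99.000248211717576
0.48999999999999999 1905.783179085736 98.101056081879534
0.495 1825.5905107420449 97.233174117656787
0.5 1881.9467040178768 96.378620208178575
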