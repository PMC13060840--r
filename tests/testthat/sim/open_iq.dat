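# q intensity sigma
0.0050000000000000001 35402.072075002907 1827.3408352381464
0.01 35945.655049310168 1780.9299575846319
0.014999999999999999 32719.926498851572 1707.3310591361023
0.02 34805.469809274473 1611.7164730652153
0.025000000000000001 30504.08461015654 1500.4831869292536
0.029999999999999999 26478.439811947777 1380.5571659540317
0.035000000000000003 25787.179728838841 1258.6830520729563
0.040000000000000001 23658.150997293604 1140.7937397875839
0.044999999999999998 21224.679787750872 1031.5370009530761
0.050000000000000003 18394.921132863976 934.0078136330402
0.055 18278.576453658818 849.70074353797145
0.059999999999999998 15876.811965082472 778.66277739351369
0.065000000000000002 13948.814332827656 719.79913837114179
0.070000000000000007 11938.686556095978 671.26708463517332
0.074999999999999997 13327.456938572732 630.88759864897213
0.080000000000000002 11903.434645758733 596.51190392112278
0.085000000000000006 11316.759776341551 566.29641321317308
0.089999999999999997 11285.837603950036 538.86200648342231
0.095000000000000001 10688.299348546259 513.33681383984299
0.10000000000000001 10076.629061285763 489.30160944803606
0.105 9762.2654086597704 466.67029822927066
0.11 9259.339941793276 445.54322076443862
0.115 8553.1358031573145 426.06830136766996
0.12 7354.3985688970624 408.33613786172975
0.125 8089.6257625756098 392.32270250399972
0.13 7536.3989303134404 377.88044416685926
0.13500000000000001 7238.5300535903116 364.76796316205076
0.14000000000000001 6535.3011838619586 352.70191857025009
0.14499999999999999 6665.0158469581529 341.41312763764495
0.14999999999999999 6752.0395186782171 330.69149006870691
0.155 6843.5363708001987 320.41008688246734
0.16 6178.5969027861174 310.52575698138486
0.16500000000000001 6137.9089697916579 301.0598309966694
0.17000000000000001 5825.6271898738214 292.06709358485426
0.17500000000000002 5281.5165351461992 283.6027184462597
0.17999999999999999 5399.5055779119702 275.69589374705214
0.185 5260.913763701602 268.33579356628411
0.19 5213.9215769974162 261.47151704081665
0.19500000000000001 5381.0078822346841 255.02376359127322
0.20000000000000001 5168.0227207731186 248.90328836893079
0.20500000000000002 4820.6182882953344 243.0301239139809
0.20999999999999999 4686.8291969887969 237.34820687297608
0.215 4798.2187476979088 231.83201615942744
0.22 4655.7641182289108 226.48442858806513
0.22500000000000001 4274.1088392382335 221.32746971834914
0.23000000000000001 4174.692544385257 216.38934800588041
0.23500000000000001 4311.01401565791 211.69175108397664
0.23999999999999999 4304.0880421333086 207.24083197290813
0.245 4037.6690697649929 203.02390180543969
0.25 4155.5920900168721 199.01205168115507
0.255 3981.0427487533802 195.16727543732804
0.26000000000000001 3711.8583233216391 191.45158739175758
0.26500000000000001 3820.7814240438493 187.83535429736671
0.27000000000000002 3477.9070311021233 184.3025780640082
0.27500000000000002 3876.204160963985 180.851951405081
0.28000000000000003 3901.38486248139 177.49380723262414
0.28500000000000003 3420.8981147218105 174.24421666149985
0.28999999999999998 3243.6928839882526 171.11816422221955
0.29499999999999998 3458.2594529088465 168.12380117690688
0.29999999999999999 3282.8666926419469 165.25928600253235
0.30499999999999999 3640.5508418043396 162.51285423782301
0.31 3191.0427303582701 159.86579322607008
0.315 3254.4382543843167 157.29720889044668
0.32000000000000001 3100.1157399835097 154.78906559955399
0.32500000000000001 2933.3778952494731 152.33003651495594
0.33000000000000002 3026.6465080994567 149.91716508828836
0.33500000000000002 2684.7701354075293 147.5550442919326
0.34000000000000002 3117.9351718288372 145.25295022361342
0.34500000000000003 2882.3367017107958 143.02091346441298
0.35000000000000003 3123.365687184446 140.86593557940714
0.35499999999999998 2841.7841262563934 138.78942168669482
0.35999999999999999 2638.6183283015312 136.78646971365683
0.36499999999999999 2779.2962071787515 134.84707717291403
0.37 2534.9789799123032 132.95877273134914
0.375 2457.8325218516393 131.10980780046134
0.38 2623.5205593320666 129.2919454277214
0.38500000000000001 2493.5207323779823 127.50206815037942
0.39000000000000001 2514.9834031931046 125.74222069121498
0.39500000000000002 2489.583282455565 124.01818033552712
0.40000000000000002 2374.6210492333994 122.33706559483699
0.40500000000000003 2345.4537270668638 120.70473684055877
0.41000000000000003 2366.3720757969072 119.12375298770695
0.41500000000000004 2490.3828877975939 117.59243826888419
0.41999999999999998 2145.2110274075162 116.10525712600277
0.42499999999999999 2361.184582351892 114.65430475730518
0.42999999999999999 2302.3286455303569 113.23141027235729
0.435 2355.4907334380482 111.83020313417614
0.44 2175.3545071583567 110.44754371811518
0.44500000000000001 2222.0418924487458 109.08393915508015
0.45000000000000001 2183.6356444221374 107.74288253908172
0.45500000000000002 2070.8473340790943 106.42936995836646
0.46000000000000002 2229.9664595463532 105.14807428765819
0.46500000000000002 2198.6023876615855 103.90172756121629
0.47000000000000003 2125.7085085734357 102.69017240907756
0.47500000000000003 2191.2864358298725 101.51032296813915
0.47999999999999998 2063.1879734964136 100.35699763046546
0.48499999999999999 1857.8176625762223 99.224333692900998
0.48999999999999999 1905.9052411148532 98.107339280354211
0.495 1821.2711683190612 97.003120679376664
0.5 1872.8242908223237 95.91144141141497
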