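no,region,statistic,objects,model,re_printed
1,Anzhen Sub-district,48467,711,46031.227,-5.03
2,Olympic Village Sub-district,57509,1771,55101.244,-4.19
3,Changying Sub-district,24770,1240,32120.220,29.67
4,Chaowai Sub-district,43162,496,39569.780,-8.32
5,Chaoyangbalizhuang Sub-district,85897,1049,61229.257,-28.72
6,Cuigezhuang Sub-district,24448,4691,30771.512,25.87
7,Datun Sub-district,71615,2345,77291.336,7.93
8,Dongba Village,37907,4732,38612.750,1.86
9,Dongfeng Sub-district,30926,1187,37596.391,21.57
10,Dougezhuang Village,12719,2178,18841.690,48.14
11,Fatou Sub-district,31964,735,29591.992,-7.42
12,Gaobeidian District,48234,2969,71468.861,48.17
13,Guanzhuang Sub-district,57269,2853,73120.667,27.68
14,Hepingjie Sub-district,98710,881,59449.281,-39.77
15,Heizhuanghu Village,49681,3806,51199.561,3.06
16,Hujialou Sub-district,64264,416,49410.197,-23.11
17,Jianwai Sub-district,42302,1265,54101.568,27.89
18,Jiangtai Sub-district,26119,2200,28267.330,8.23
19,Jianzhan Sub-district,59144,6891,60010.514,1.47
20,Jingsong Sub-district,73200,1003,59991.594,-18.04
21,Jiuxianqiao Sub-district,69146,1297,70233.239,1.57
22,Laiguangying Sub-district,47269,3889,51471.291,8.89
23,Liulitun Sub-district,62168,891,48996.313,-21.19
24,Maizidian Sub-district,21674,954,24664.127,13.80
25,Nanmofang Sub-district,59499,2014,70155.476,17.91
26,Panjiayuan Sub-district,81055,762,59981.261,-26.00
27,Pingfang Sub-district,33492,2673,46781.497,39.08
28,Sanjianfang Sub-district,71011,1443,78501.201,10.55
29,Sanlitun Sub-district,38285,728,36799.497,-3.88
30,Shibalidian Sub-district,38950,6658,41719.462,7.11
31,Beijing Airport Sub-district,24735,832,25184.881,1.82
32,Shuangjing Sub-district,72360,1063,66849.199,-7.62
33,Sunhe Sub-district,21979,3760,26109.591,18.79
34,Taiyanggong Sub-district,45381,1147,48487.497,6.85
35,Tuanjiehu Sub-district,36869,264,33996.495,-7.79
36,Wangsiying Village,19517,2394,27106.487,38.89
37,Wangjing Sub-district,82815,2321,82599.481,-0.26
38,Xiangheyuan Sub-district,34636,350,32841.498,-5.18
39,Xiaoguan Sub-district,51401,663,45998.869,-10.51
40,Xiaohongmen Sub-district,29112,2100,40009.487,37.43
41,Yayuncun Sub-district,48858,858,53299.819,9.09
42,Zuojiazhuang Sub-district,67016,799,59996.794,-10.47
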