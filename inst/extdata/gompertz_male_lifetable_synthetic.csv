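age,qx
0,2.62256706079571e-05
1,2.88392532278856e-05
2,3.17132946134252e-05
3,3.48737501368353e-05
4,3.83491615077791e-05
5,4.21709144525014e-05
6,4.63735220579026e-05
7,5.09949363350779e-05
8,5.6076890810819e-05
9,6.16652772346631e-05
10,6.78105597958168e-05
11,7.4568230581378e-05
12,8.19993103777446e-05
13,9.01708993241741e-05
14,9.91567823747389e-05
15,0.000109038095016372
16,0.00011990405523057
17,0.000131852768279383
18,0.00014499211154773
19,0.000159440707389431
20,0.000175328992709981
21,0.000192800394881508
22,0.000212012624532276
23,0.000233139096792227
24,0.000256370493716503
25,0.000281916481860013
26,0.000310007600348456
27,0.00034089733629617
28,0.000374864406070842
29,0.000412215262713316
30,0.000453286851801289
31,0.000498449640215085
32,0.000548110944637928
33,0.0006027185892213
34,0.000662764924686737
35,0.000728791244240428
36,0.000801392635068113
37,0.000881223307878645
38,0.000969002451000917
39,0.00106552065993577
40,0.00117164699805122
41,0.00128833674931217
42,0.00141663992958663
43,0.00155771062919585
44,0.00171281726600794
45,0.00188335383554026
46,0.00207085225226344
47,0.00227699588461175
48,0.00250363439512453
49,0.0027528000066823
50,0.00302672532596744
51,0.00332786286607108
52,0.00365890642156275
53,0.00402281446130825
54,0.00442283571679838
55,0.00486253715665879
56,0.00534583455121588
57,0.00587702584433705
58,0.00646082756301141
59,0.00710241450800706
60,0.00780746298104676
61,0.00858219781480699
62,0.00943344348106812
63,0.0103686795587545
64,0.0113961008464812
65,0.0125246824023901
66,0.0137642497861198
67,0.0151255547619566
68,0.0166203566964734
69,0.0182615098457595
70,0.0200630566736216
71,0.0220403272692966
72,0.0242100448369338
73,0.0265904371043316
74,0.029201353339169
75,0.032064386460315
76,0.0352029994817362
77,0.0386426552177939
78,0.0424109478009504
79,0.0465377341043022
80,0.0510552626090785
81,0.0559982965971501
82,0.0614042277659076
83,0.067313175442253
84,0.0737680654990712
85,0.0808146818378073
86,0.0885016818839471
87,0.0968805659427634
88,0.106005588482284
89,0.115933597462773
90,0.12672378574651
91,0.138437336449811
92,0.151136941922489
93,0.164886173977888
94,0.179748681217286
95,0.195787188025025
96,0.213062269356309
97,0.231630876183862
98,0.251544588893176
99,0.272847580598827
100,0.295574279972198
101,0.319746734481496
102,0.345371690746357
103,0.372437429779724
104,0.400910421880053
105,0.430731899220969
106,0.461814483653873
107,0.494039052030035
108,0.527252069528413
109,0.561263669685701
110,1
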