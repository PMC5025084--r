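"index","value"
1,8489.98765383561
2,146.599698814691
3,625785.084166223
4,93.9822184340988
5,2497.66659664636
6,11.7350479083541
7,5.93170946092151
8,39246.8935845223
9,202.844108164279
10,1258.56198585968
11,1271.60079617998
12,1298.83721795357
13,3866.48374867641
14,396.466177195175
15,3.53382280369546
16,323.924972128551
17,6.07502786891922
18,8490.99157438475
19,175.116854408983
20,663261.579812456
21,99.6223707563422
22,2475.227391915
23,12.2336905178372
24,5.95208790511493
25,37165.9682299302
26,202.648697347951
27,1187.94350456478
28,1269.72780220891
29,1371.32869322721
30,3874.50636211964
31,396.539727685965
32,3.46027231238318
33,324.55879202391
34,5.44120797721374
35,8489.96972857704
36,208.789971821352
37,693345.218900556
38,106.420875133885
39,2454.78315325727
40,12.9514240070423
41,6.16629992656786
42,35616.3038070527
43,202.749631621648
44,1126.04074246082
45,1265.70580295284
46,1437.25345458563
47,3880.12091424086
48,396.57623465918
49,3.42376533948174
50,325.15958432428
51,4.84041567264003
52,8486.80649560606
53,248.088872969181
54,713748.409703393
55,114.008750404028
56,2436.48836784573
57,13.9136240197747
58,6.60016432492035
59,34404.2270219995
60,203.062187980402
61,1069.48146037321
62,1259.95652819191
63,1499.56201143987
64,3883.90304559939
65,396.573084839498
66,3.42691515895185
67,325.730969591931
68,4.26903040684827
69,8481.64051534067
70,293.669186592666
71,723074.936144844
72,122.014306747901
73,2420.47563411098
74,15.1643923151064
75,7.31176830179482
76,33403.4203396454
77,203.561423707337
78,1015.62441371256
79,1252.52407470187
80,1560.8515115833
81,3886.32635418282
82,396.533433179512
83,3.46656681901812
84,326.276232381434
85,3.72376761874074
86,8474.87453847125
87,346.725458916063
88,720909.926955168
89,130.166558069041
90,2406.87968946318
91,16.7670620274531
92,8.40986932072283
93,32567.7698262745
94,204.290092476525
95,962.068376371863
96,1243.12348864797
97,1623.80813496437
98,3887.86741377151
99,396.467078029844
100,3.53292196936439
101,326.798338829756
102,3.20166117280975
103,8467.08835613393
104,409.168522321905
105,707069.567635448
106,138.282560146651
107,2395.82994108416
108,18.7919772220901
109,10.0742902941212
110,31907.3119775642
111,205.360281536604
112,906.172430281942
113,1231.05155546945
114,1691.77601425229
115,3889.29586880815
116,396.387258684573
117,3.61274131409156
118,327.299969455089
119,2.70003054536669
120,8458.92662308566
121,483.447649512286
122,680411.240010025
123,146.188253057981
124,2387.38961367049
125,21.2785508828582
126,12.5586705073226
127,31452.161242387
128,206.954119262274
129,844.920770262027
130,1215.02470560316
131,1769.05452410963
132,3892.13429162137
133,396.305496886239
134,3.69450311354105
135,327.783560013553
136,2.21643998772345
137,8299.97627349266
138,2708.80966032222
139,18.8328923848371
140,316.343944581119
141,303.094617559055
142,0.637454073996566
143,0.0100026192336846
144,8314.72705319191
145,2670.41565536675
146,17.5783958638907
147,316.917221953587
148,302.161060565093
149,0.576882420964279
150,0.00972379322703131
151,8328.37177827595
152,2634.5714500678
153,16.4639335150751
154,317.470680029483
155,301.236557904208
156,0.522066256717929
157,0.00945274036021283
158,8340.8408705107
159,2601.30427553383
160,15.4753392984944
161,318.008130577197
162,300.323997977272
163,0.472458707265482
164,0.00918924391133475
165,8352.07888900306
166,2570.65253066009
167,14.6011409234171
168,318.532010982608
169,299.425884164855
170,0.427564860465575
171,0.00893309320148877
172,8362.06179924211
173,2542.66433946224
174,13.8330740597809
175,319.044298120872
176,298.545263026494
177,0.38693682890112
178,0.00868408342623629
179,8370.80708884746
180,2517.39478400535
181,13.1673833164211
182,319.547221293875
183,297.686646009743
184,0.350169281842929
185,0.00844201549179175
186,8378.37547944456
187,2494.89243736798
188,12.6074360513685
189,320.043529898143
190,296.856886364669
191,0.316895401734599
192,0.00820669585577455
193,8284.18537292409
194,2749.7437656045
195,20.2441767046315
196,315.745108112043
197,304.033126345921
198,0.704385507121637
199,0.0102894413184043
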