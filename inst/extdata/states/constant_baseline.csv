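"index","value"
1,5130.89801797615
2,47.7147971676445
3,239540.035025653
4,74.3183615320333
5,902.221692461385
6,43.2042759934591
7,303.117268884268
8,94602.3847098937
9,922.363969599136
10,2575.13869503531
11,900.651117061459
12,353.210188291871
13,3566.79376069
14,394.976582762362
15,5.02341723658562
16,323.880443580675
17,6.11955636887455
18,5125.7268592782
19,52.0310792543303
20,256527.114838778
21,72.6609722894365
22,877.226611140455
23,42.8120505062327
24,283.877070104034
25,87630.3081933332
26,875.086287254565
27,2322.6645037336
28,1019.68438843214
29,486.651108432259
30,3595.54776476888
31,394.901009973809
32,5.0989900290028
33,324.612673213769
34,5.38732679143283
35,5119.89092869732
36,57.1043175538639
37,273108.997075369
38,71.1580961631064
39,854.588557523773
40,42.8708889600766
41,267.539134250286
42,81579.292212463
43,843.222833619387
44,2080.73036671317
45,1112.9697120171
46,635.299921873403
47,3625.2818839348
48,394.847529619149
49,5.15247038080805
50,325.299204769106
51,4.70079522798351
52,5113.48161436912
53,63.1559717082811
54,289253.04042585
55,69.9451593793401
56,834.201835457823
57,43.2672865321509
58,253.035529465971
59,76305.5605945811
60,823.006524034534
61,1853.73361956578
62,1181.32759138533
63,793.93878960985
64,3655.54130674539
65,394.813868520283
66,5.18613148178988
67,325.941330180647
68,4.05866976404529
69,5106.53869729262
70,70.452193004875
71,304598.673577329
72,69.2000401443645
73,815.976034409823
74,43.9449726887801
75,239.759248860187
76,71761.9009834631
77,812.740077734715
78,1642.70931705546
79,1227.15641437272
80,959.13426856176
81,3686.04871827812
82,394.79831014517
83,5.20168985370803
84,326.540287211848
85,3.45971274063649
86,5099.05375035072
87,79.3076620491104
88,318331.43315835
89,69.1543707331965
90,799.839685784603
91,44.8820207981226
92,227.329916318983
93,67949.981262923
94,811.87884413138
95,1447.2597232586
96,1253.00427309454
97,1128.73600392716
98,3716.61209955641
99,394.79965409491
100,5.20034589566744
101,327.097415693397
102,2.90258429035683
103,5090.97194047858
104,90.0761859642816
105,328881.993645454
106,70.0874592335907
107,785.745861502103
108,46.0803177384996
109,215.497477655462
110,64884.5791402628
111,820.652125368207
112,1266.50216343783
113,1261.08641336928
114,1301.41142354012
115,3747.07341899624
116,394.818155695545
117,5.1818443072774
118,327.614274577846
119,2.38572541611867
120,5082.20511144562
121,103.12253141757
122,333259.624934556
123,72.2896771777259
124,773.674874786615
125,47.5658652543857
126,204.110169582475
127,62553.57122306
128,839.888185734351
129,1099.5236904099
130,1253.19452545641
131,1476.28178453366
132,3777.27955333457
133,394.858620009601
134,5.14138000135999
135,328.092730941195
136,1.90726905980416
137,5039.08150081186
138,965.244642862198
139,424.605630027823
140,1053.46337011554
141,173981.545858458
142,0.0883829712017673
143,0.0382032708661718
144,5046.89236668572
145,933.421041553678
146,416.6455337433
147,1054.12747086
148,173979.76851054
149,0.079947846080556
150,0.0371523933408857
151,5053.47280007987
152,904.525899769817
153,409.255509600645
154,1054.75754334386
155,173977.936745629
156,0.0723177554002898
157,0.0361304228580626
158,5058.8824957337
159,878.428411099191
160,402.441224611442
161,1055.35549385562
162,173976.068606991
163,0.0654158680005777
164,0.0351365642564359
165,5063.1790899014
166,854.992961783125
167,396.203659627209
168,1055.92370323397
169,173974.181411879
170,0.0591726853603625
171,0.0341700442476595
172,5066.4140474677
173,834.090436851244
174,390.539693979737
175,1056.46532256374
176,173972.292599759
177,0.0535253417829071
178,0.0332301108146379
179,5068.62906291654
180,815.60766753565
181,385.442455054622
182,1056.98436539209
183,173970.420126828
184,0.0484169713699718
185,0.0323160326264064
186,5069.85394404376
187,799.454279236861
188,380.902074255047
189,1057.48546020229
190,173968.582464963
191,0.043796135410933
192,0.031427098469107
193,5029.98328740968
194,1000.10802498652
195,433.123878421614
196,1052.76336429492
197,173983.248423426
198,0.097708068214639
199,0.0392838730867963
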