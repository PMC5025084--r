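"index","value"
1,2850.66902683827
2,50.6502659647188
3,289531.322638545
4,63.9605083902407
5,644.023955860705
6,7.45466696200182
7,6.19191562053908
8,20744.9113580993
9,188.380927109867
10,811.029061451255
11,1206.86999069418
12,1811.10094785565
13,3902.72113907424
14,396.227018826807
15,3.7729811724096
16,323.388643647716
17,6.61135635018463
18,2872.23593799465
19,57.2478944785342
20,332730.38009081
21,62.6218303676379
22,620.703132374681
23,7.63016059456109
24,6.2595961722205
25,21352.5051396558
26,189.565333724733
27,769.02963443132
28,1193.39910858439
29,1866.57125695535
30,3910.7966191741
31,396.467011904191
32,3.53298809452353
33,324.202974359128
34,5.79702564225261
35,2891.57500872416
36,64.6131537152702
37,369123.027401545
38,61.6198747182795
39,599.425827070868
40,7.90056456926603
41,6.43671603496227
42,22172.4301842875
43,190.792787101197
44,731.952711702546
45,1180.12747236927
46,1916.91981590993
47,3917.29574428011
48,396.725273568374
49,3.27472643041437
50,324.962349830262
51,5.03765016694754
52,2908.36086840813
53,72.8835235486779
54,399676.786177168
55,61.0540662618948
56,580.112163726853
57,8.28501041626673
58,6.75185994414696
59,23168.2583947599
60,192.078181653607
61,698.630722174483
62,1167.00843745903
63,1963.36084035073
64,3922.27430275452
65,396.951122024682
66,3.04887797355003
67,325.669226716158
68,4.33077328303844
69,2922.34020664719
70,82.2542488393687
71,424412.444599166
72,61.0579236848796
73,562.698427028496
74,8.80817864571782
75,7.24637744307259
76,24277.9449311972
77,193.434626316978
78,667.918371985992
79,1153.83990329262
80,2007.2417246922
81,3925.81083229833
82,397.12359162627
83,2.87640837212397
84,326.325751795674
85,3.67424820450676
86,2933.33128167956
87,93.0000730009931
88,442788.303693534
89,61.8063038781897
90,547.142438999769
91,9.50181735441751
92,7.98285245741178
93,25426.0029460487
94,194.882971682584
95,638.566508077558
96,1140.21736661356
97,2050.21612530914
98,3928.01160198937
99,397.236924919354
100,2.76307507994536
101,326.93385469275
102,3.06614530986044
103,2941.20266543067
104,105.487614027381
105,453748.338555269
106,63.5155910377396
107,533.427982915234
108,10.4064821338371
109,9.06021051014918
110,26544.5210339479
111,196.468679320667
112,609.158363732372
113,1125.48367557632
114,2094.3579607011
115,3929.02205816118
116,397.293955691645
117,2.70604430691289
118,327.495348596463
119,2.50465140438707
120,2945.84596081866
121,120.164564641198
122,455304.257727827
123,66.4214706954294
124,521.565502782287
125,11.5699449760434
126,10.6349730264301
127,27589.9642725328
128,198.28703293312
129,578.007995918722
130,1108.62479125342
131,2142.36721280179
132,3929.09771755041
133,397.303900102676
134,2.69609989683458
135,328.012045648244
136,1.9879543531233
137,2678.00750867049
138,688.580517499224
139,24.277194504456
140,442.965031127638
141,271.504910996511
142,0.0546425081429957
143,0.0634197930029775
144,2699.84044001238
145,660.396396892431
146,22.7609578162611
147,443.256416929591
148,270.647231447994
149,0.0494301173009134
150,0.0616682212106499
151,2721.36079694268
152,634.761275406507
153,21.399092058451
154,443.561982862259
155,269.815932067562
156,0.0447149440533632
157,0.0599650194058735
158,2742.32706099286
159,611.522726728174
160,20.1778465069225
161,443.884417888022
162,269.011508520052
163,0.0404495577454431
164,0.0583088520059548
165,2762.49786444608
166,590.549625396084
167,19.0854778435879
168,444.225187356042
169,268.234622994447
170,0.0365910522663281
171,0.0566984203016832
172,2781.63943549336
173,571.735402081248
174,18.1124030702355
175,444.584416610428
176,267.486208127273
177,0.0331006144372348
178,0.0551324614394246
179,2799.52985357413
180,555.0014067815
181,17.2517011799503
182,444.961141846526
183,266.767806309437
184,0.0299431335726449
185,0.0536097474313115
186,2815.95985996842
187,540.298656148252
188,16.5002876448325
189,445.35379121365
190,266.082244577844
191,0.0270868482870735
192,0.0521290841927547
193,2656.09511956922
194,719.48496394615
195,25.9635945886071
196,442.6843055596
197,272.388676440215
198,0.0604045489057966
199,0.0652211082858332
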