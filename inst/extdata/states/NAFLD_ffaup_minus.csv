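"index","value"
1,8443.85721627164
2,127.436249823732
3,584284.552916153
4,86.5369474102341
5,2307.66697920192
6,10.6445527680272
7,29.3756540632889
8,74563.9917652323
9,315.73635407028
10,1054.74292881379
11,1248.35542606009
12,1525.90164512433
13,3697.49642556044
14,396.236348698473
15,3.76365130054135
16,324.045888898824
17,5.9541110986457
18,8443.27693212702
19,146.839450950716
20,614273.204503555
21,88.8057130578337
22,2284.16682456837
23,10.3437040788244
24,37.272519755644
25,81528.1781504282
26,335.94716924278
27,934.176034478181
28,1226.54056650778
29,1668.28339901704
30,3702.65403929376
31,396.261628622191
32,3.73837137622003
33,324.669525831725
34,5.33047416927572
35,8441.60286678721
36,167.889856493293
37,638297.887560006
38,91.3463847953389
39,2261.99806416817
40,9.93303119405564
41,45.3425924645121
42,88611.758743013
43,360.709756050309
44,820.053353702299
45,1196.09456860313
46,1812.85207769768
47,3716.92286128599
48,396.248550984311
49,3.75144901424394
50,325.260510278027
51,4.73948971911393
52,8439.00200378519
53,190.605166243412
54,655405.495569954
55,94.0723400062882
56,2241.06310020217
57,9.49688087968717
58,53.2023890191145
59,95451.8354294528
60,389.841421906478
61,717.436258652528
62,1159.17622264848
63,1952.38751870059
64,3736.9881688008
65,396.195492281522
66,3.80450771682983
67,325.822455587954
68,4.1775444104867
69,8435.63259147219
70,215.045961323049
71,664724.976894498
72,96.8843639841975
73,2221.27345299373
74,9.08280120684411
75,60.7044489353365
76,101801.234572698
77,423.143850390655
78,627.319975013346
79,1117.94178261118
80,2083.73824237079
81,3760.3056674984
82,396.101483926538
83,3.89851607233043
84,326.358578058313
85,3.64142194186019
86,8431.6593127075
87,241.365899279917
88,665391.453312474
89,99.6997656460621
90,2202.54438452271
91,8.71352126227996
92,67.8228335945928
93,107498.126809288
94,460.331570059503
95,548.85285576731
96,1074.05912023247
97,2206.08802398725
98,3785.18596059648
99,395.966173681483
100,4.03382631807377
101,326.871736223455
102,3.12826377904931
103,8427.25278473424
104,269.881119123126
105,656294.992538411
106,102.471937350874
107,2184.79556362876
108,8.39909246863477
109,74.5853843307426
110,112446.436036681
111,500.981918798041
112,480.583328516803
113,1028.67526586446
114,2319.74140562213
115,3810.54675782494
116,395.790094923279
117,4.20990507529948
118,327.364463501282
119,2.63553649896048
120,8422.58218592791
121,301.167217007898
122,635519.580987092
123,105.199101490044
124,2167.95421643115
125,8.144919534918
126,81.054831947902
127,116633.035795515
128,544.671453501818
129,421.022681343371
130,982.532316797308
131,2425.44500183833
132,3835.70224021036
133,395.575776754921
134,4.42422324470384
135,327.838998120699
136,2.16100188068365
137,8265.57814542144
138,2493.51419756735
139,27.0583212734431
140,398.279995866353
141,454.940016414894
142,0.631227524850383
143,0.010076427400228
144,8279.44381313569
145,2456.05705756654
146,26.1175939286002
147,399.188108658078
148,454.392793366632
149,0.571251555875831
150,0.00979550449077987
151,8292.21747824925
152,2420.91928893939
153,25.519732319589
154,400.135123896719
155,454.020682452326
156,0.516974089958794
157,0.0095224142905511
158,8303.91247221872
159,2387.98549709399
160,25.2727712408063
161,401.116264769129
162,453.833036948149
163,0.467853704378423
164,0.00925693838550988
165,8314.55194368879
166,2357.13394867932
167,25.3675478836308
168,402.126413524015
169,453.832380712545
170,0.423400416816525
171,0.00899886445267374
172,8324.16863747826
173,2328.23931491425
174,25.7846943919701
175,403.160620069496
176,454.015518733416
177,0.383170798108802
178,0.00874798609022804
179,8332.80466376504
180,2301.17512108356
181,26.4999084887388
182,404.214327083072
183,454.374641831996
184,0.346763549315394
185,0.00850410265238306
186,8340.51077823508
187,2275.81639858674
188,27.4880548691642
189,405.283566960755
190,454.89902503825
191,0.313815498998287
192,0.00826701908883725
193,8250.61834317481
194,2533.39537129303
195,28.3103787607186
196,397.414182929432
197,455.6449631679
198,0.697500260317231
199,0.0103654076987328
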