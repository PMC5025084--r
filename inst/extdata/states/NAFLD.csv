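"index","value"
1,8445.5612413191
2,129.947468059892
3,588521.916423701
4,87.9112738710994
5,2303.17882442839
6,11.9022732177698
7,39.362075775208
8,94036.1577349559
9,347.756706885615
10,1142.47645791038
11,1255.21385721974
12,1431.30968486883
13,3666.21450576365
14,396.291772936291
15,3.70822706283029
16,324.04947287689
17,5.95052712059643
18,8444.79330959601
19,149.04752375519
20,617867.028794599
21,89.8515797172369
22,2279.79594987291
23,11.0795976023241
24,44.4482739207516
25,95188.4741795503
26,361.038510891554
27,980.592453903042
28,1234.22584222018
29,1614.18170387976
30,3686.05999327311
31,396.306464591922
32,3.69353540714376
33,324.672657264691
34,5.32734273645798
35,8442.96439119697
36,169.521805850135
37,640744.895931759
38,92.0315866364948
39,2257.68701162345
40,10.3054780903573
41,49.5663185570186
42,96586.9972103515
43,377.035315791707
44,841.354991791458
45,1201.57204042087
46,1786.07296779157
47,3709.41572310591
48,396.278881295022
49,3.72111870362622
50,325.26325803031
51,4.73674196672284
52,8440.2399679028
53,191.18050050412
54,656190.602636011
55,94.2824485601097
56,2236.74776410388
57,9.59105402195405
58,54.4211269356164
59,97697.0374838941
60,394.672626286494
61,722.280638382778
62,1160.87269783001
63,1945.84666379329
64,3735.27627109283
65,396.205662467592
66,3.79433753080419
67,325.824878557268
68,4.17512144133432
69,8436.84125419311
70,213.930011594737
71,663530.405650348
72,96.4715047432604
73,2216.86282973579
74,8.94166261993279
75,58.838561924034
76,98143.4584582178
77,412.874481426359
78,620.675376937207
79,1114.95415302831
80,2093.37047003215
81,3762.52880394841
82,396.085003782521
83,3.91499621671208
84,326.360733178235
85,3.63926682198783
86,8433.01341708763
87,237.84029250367
88,662211.404641717
89,98.5236218366032
90,2197.91492485384
91,8.35747070867325
92,62.7350928067511
93,97713.9929781564
94,430.668698491078
95,533.920735387436
96,1065.89437311284
97,2229.18489148938
98,3790.20682386875
99,395.91622429035
100,4.08377570919992
101,326.873674702053
102,3.12632530082772
103,8428.99222575092
104,263.205247501267
105,651433.975254828
106,100.424519220634
107,2179.7921038938
108,7.83587800880364
109,66.0859350712726
110,96335.0477164228
111,447.277857718244
112,459.677649419103
113,1015.16678243892
114,2354.15556814654
115,3817.55572256268
116,395.699439007961
117,4.3005609909549
118,327.366223599646
119,2.63377640086899
120,8424.97854868985
121,290.623080371557
122,629514.598254111
123,102.2166510621
124,2162.39407517648
125,7.37393220077042
126,68.9134955713142
127,94064.682188391
128,462.273117682609
129,395.975620348153
130,963.812824015649
131,2469.21155561687
132,3844.01982758676
133,395.436320057138
134,4.56367994248524
135,327.840597707612
136,2.15940229379032
137,8266.79986484103
138,2488.69078745012
139,26.8855026605581
140,398.204608297557
141,453.734758136187
142,0.631445697414196
143,0.0100738206320795
144,8280.68459664262
145,2451.24173715204
146,25.9900559330613
147,399.185488850101
148,453.368278844565
149,0.571448851948835
150,0.00979297184223934
151,8293.46533007596
152,2416.12729729721
153,25.4367507743234
154,400.172597162815
155,453.106161693585
156,0.517152507089124
157,0.0095199536541678
158,8305.15841610902
159,2383.21692560555
160,25.2035965311371
161,401.164458067668
162,452.951456393163
163,0.468015048988399
164,0.00925454771375282
165,8315.79418009886
166,2352.37083219065
167,25.2616353425565
168,402.157907656277
169,452.900069364321
170,0.423546322488862
171,0.00899654175622802
172,8325.41763497271
173,2323.44217011513
174,25.5788855444165
175,403.148840653186
176,452.942980534681
177,0.383302742123335
178,0.00874572943633974
179,8334.08683930869
180,2296.28031593286
181,26.1234855504094
182,404.132734398133
183,453.06839928819
184,0.346882867603695
185,0.0085019101632511
186,8341.86960236016
187,2270.73485897959
188,26.8663472947456
189,405.105112033683
190,453.264015744119
191,0.313923399667513
192,0.00826488894005106
193,8251.80563542397
194,2528.5953056743
195,28.1345716455953
196,397.22886515769
197,454.193607549487
198,0.697741518266581
199,0.0103627246418525
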