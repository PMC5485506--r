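"age","q"
0,0.000429907563249787
1,0.000432906269029032
2,0.000436204834995624
3,0.000439833244986532
4,0.000443824480763855
5,0.000448214821711757
6,0.000453044174481776
7,0.000458356435579121
8,0.000464199890177208
9,0.000470627650778432
10,0.000477698139697447
11,0.000485475619740661
12,0.000494030777889898
13,0.000503441367277646
14,0.000513792913267808
15,0.000525179490031169
16,0.000537704574643527
17,0.000551481986428182
18,0.000566636920034669
19,0.000583307081584383
20,0.00060164393813944
21,0.000621814091765982
22,0.000644000790578025
23,0.000668405590369736
24,0.000695250181786511
25,0.000724778399458836
26,0.000757258431136276
27,0.000792985246628963
28,0.000832283268307199
29,0.000875509307033617
30,0.000923055789731841
31,0.000975354307344301
32,0.00103287951472408
33,0.00109615341704994
34,0.00116575008069442
35,0.0012423008101089
36,0.00132649983626631
37,0.00141911056653266
38,0.00152097245055516
39,0.00163300852189063
40,0.00175623368067601
41,0.0018917637886976
42,0.00204082565477892
43,0.00220476799550207
44,0.00238507346394456
45,0.00258337184736646
46,0.00280145454365255
47,0.00304129043581947
48,0.00330504329404424
49,0.00359509084546084
50,0.00391404566340037
51,0.00426477803977943
52,0.00465044101693102
53,0.00507449776823976
54,0.00554075153038003
55,0.00605337830361163
56,0.00661696255025213
57,0.00723653613485054
58,0.00791762076237668
59,0.00866627418247523
60,0.00948914043792526
61,0.0103935044431998
62,0.0113873511835281
63,0.0124794298250372
64,0.0136793230210235
65,0.0149975216865363
66,0.0164455054912254
67,0.0180358292863791
68,0.0197822156333408
69,0.0216996535335298
70,0.0238045033709435
71,0.0261146079613411
72,0.0286494094525053
73,0.0314300716302539
74,0.0344796069473559
75,0.0378230072981312
76,0.04148737719996
77,0.0455020676025456
78,0.0498988080136468
79,0.054711833991983
80,0.0599780062990128
81,0.0657369171056148
82,0.0720309776017395
83,0.0789054801422512
84,0.0864086266682431
85,0.0945915135622631
86,0.103508061327247
87,0.113214875532173
88,0.123771023367183
89,0.135237707942712
90,0.147677820224611
91,0.161155346330748
92,0.175734605981747
93,0.191479296415696
94,0.208451315331682
95,0.226709336791874
96,0.246307115953617
97,0.267291502591172
98,0.289700150272954
99,0.313558918545274
100,0.338878980356319
101,0.365653667051685
102,0.393855109305319
103,0.423430764797339
104,0.454299962353284
105,0.486350636957634
106,0.519436478866415
107,0.553374769904959
108,0.587945226136164
109,0.622890201570154
110,0.65791662345321
111,0.692700014986863
112,0.726890903972886
113,0.76012380404506
114,0.792028779704266
115,0.822245364183947
116,0.85043829713531
117,0.876314208335193
118,0.899638032591238
119,0.920247656293299
120,1
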