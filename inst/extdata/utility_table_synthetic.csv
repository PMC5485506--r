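"age","utility"
0,1
1,1
2,1
3,1
4,1
5,1
6,1
7,1
8,1
9,1
10,1
11,1
12,1
13,1
14,1
15,1
16,1
17,1
18,1
19,1
20,1
21,1
22,1
23,1
24,1
25,1
26,1
27,1
28,1
29,1
30,1
31,1
32,1
33,1
34,1
35,1
36,0.996
37,0.992
38,0.988
39,0.984
40,0.98
41,0.976
42,0.972
43,0.968
44,0.964
45,0.96
46,0.956
47,0.952
48,0.948
49,0.944
50,0.94
51,0.936
52,0.932
53,0.928
54,0.924
55,0.92
56,0.916
57,0.912
58,0.908
59,0.904
60,0.9
61,0.896
62,0.892
63,0.888
64,0.884
65,0.88
66,0.876
67,0.872
68,0.868
69,0.864
70,0.86
71,0.856
72,0.852
73,0.848
74,0.844
75,0.84
76,0.836
77,0.832
78,0.828
79,0.824
80,0.82
81,0.816
82,0.812
83,0.808
84,0.804
85,0.8
86,0.796
87,0.792
88,0.788
89,0.784
90,0.78
91,0.78
92,0.78
93,0.78
94,0.78
95,0.78
96,0.78
97,0.78
98,0.78
99,0.78
100,0.78
101,0.78
102,0.78
103,0.78
104,0.78
105,0.78
106,0.78
107,0.78
108,0.78
109,0.78
110,0.78
111,0.78
112,0.78
113,0.78
114,0.78
115,0.78
116,0.78
117,0.78
118,0.78
119,0.78
120,0.78
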