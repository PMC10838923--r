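roi_index,network
0,FrontoParietal
1,FrontoParietal
2,FrontoParietal
3,FrontoParietal
4,FrontoParietal
5,FrontoParietal
6,FrontoParietal
7,FrontoParietal
8,FrontoParietal
9,FrontoParietal
10,FrontoParietal
11,FrontoParietal
12,FrontoParietal
13,FrontoParietal
14,FrontoParietal
15,FrontoParietal
16,FrontoParietal
17,FrontoParietal
18,FrontoParietal
19,CinguloOpercular
20,CinguloOpercular
21,CinguloOpercular
22,CinguloOpercular
23,CinguloOpercular
24,CinguloOpercular
25,CinguloOpercular
26,CinguloOpercular
27,CinguloOpercular
28,CinguloOpercular
29,CinguloOpercular
30,CinguloOpercular
31,CinguloOpercular
32,CinguloOpercular
33,CinguloOpercular
34,CinguloOpercular
35,CinguloOpercular
36,CinguloOpercular
37,CinguloOpercular
38,DorsalAttention
39,DorsalAttention
40,DorsalAttention
41,DorsalAttention
42,DorsalAttention
43,DorsalAttention
44,DorsalAttention
45,DorsalAttention
46,DorsalAttention
47,DorsalAttention
48,DorsalAttention
49,DorsalAttention
50,DorsalAttention
51,DorsalAttention
52,DorsalAttention
53,DorsalAttention
54,DorsalAttention
55,DorsalAttention
56,DorsalAttention
57,VentralAttention
58,VentralAttention
59,VentralAttention
60,VentralAttention
61,VentralAttention
62,VentralAttention
63,VentralAttention
64,VentralAttention
65,VentralAttention
66,VentralAttention
67,VentralAttention
68,VentralAttention
69,VentralAttention
70,VentralAttention
71,VentralAttention
72,VentralAttention
73,VentralAttention
74,VentralAttention
75,VentralAttention
76,Salience
77,Salience
78,Salience
79,Salience
80,Salience
81,Salience
82,Salience
83,Salience
84,Salience
85,Salience
86,Salience
87,Salience
88,Salience
89,Salience
90,Salience
91,Salience
92,Salience
93,Salience
94,Salience
95,Cerebellum
96,Cerebellum
97,Cerebellum
98,Cerebellum
99,Cerebellum
100,Cerebellum
101,Cerebellum
102,Cerebellum
103,Cerebellum
104,Cerebellum
105,Cerebellum
106,Cerebellum
107,Cerebellum
108,Cerebellum
109,Cerebellum
110,Cerebellum
111,Cerebellum
112,Cerebellum
113,Cerebellum
114,DMN
115,DMN
116,DMN
117,DMN
118,DMN
119,DMN
120,DMN
121,DMN
122,DMN
123,DMN
124,DMN
125,DMN
126,DMN
127,DMN
128,DMN
129,DMN
130,DMN
131,DMN
132,DMN
133,Memory
134,Memory
135,Memory
136,Memory
137,Memory
138,Memory
139,Memory
140,Memory
141,Memory
142,Memory
143,Memory
144,Memory
145,Memory
146,Memory
147,Memory
148,Memory
149,Memory
150,Memory
151,Memory
152,Visual
153,Visual
154,Visual
155,Visual
156,Visual
157,Visual
158,Visual
159,Visual
160,Visual
161,Visual
162,Visual
163,Visual
164,Visual
165,Visual
166,Visual
167,Visual
168,Visual
169,Visual
170,Visual
171,Auditory
172,Auditory
173,Auditory
174,Auditory
175,Auditory
176,Auditory
177,Auditory
178,Auditory
179,Auditory
180,Auditory
181,Auditory
182,Auditory
183,Auditory
184,Auditory
185,Auditory
186,Auditory
187,Auditory
188,Auditory
189,Auditory
190,SensorySomatomotorHand
191,SensorySomatomotorHand
192,SensorySomatomotorHand
193,SensorySomatomotorHand
194,SensorySomatomotorHand
195,SensorySomatomotorHand
196,SensorySomatomotorHand
197,SensorySomatomotorHand
198,SensorySomatomotorHand
199,SensorySomatomotorHand
200,SensorySomatomotorHand
201,SensorySomatomotorHand
202,SensorySomatomotorHand
203,SensorySomatomotorHand
204,SensorySomatomotorHand
205,SensorySomatomotorHand
206,SensorySomatomotorHand
207,SensorySomatomotorHand
208,SensorySomatomotorHand
209,SensorySomatomotorMouth
210,SensorySomatomotorMouth
211,SensorySomatomotorMouth
212,SensorySomatomotorMouth
213,SensorySomatomotorMouth
214,SensorySomatomotorMouth
215,SensorySomatomotorMouth
216,SensorySomatomotorMouth
217,SensorySomatomotorMouth
218,SensorySomatomotorMouth
219,SensorySomatomotorMouth
220,SensorySomatomotorMouth
221,SensorySomatomotorMouth
222,SensorySomatomotorMouth
223,SensorySomatomotorMouth
224,SensorySomatomotorMouth
225,SensorySomatomotorMouth
226,SensorySomatomotorMouth
227,SensorySomatomotorMouth
228,Subcortical
229,Subcortical
230,Subcortical
231,Subcortical
232,Subcortical
233,Subcortical
234,Subcortical
235,Subcortical
236,Subcortical
237,Subcortical
238,Subcortical
239,Subcortical
240,Subcortical
241,Subcortical
242,Subcortical
243,Subcortical
244,Subcortical
245,Subcortical
246,Uncertain
247,Uncertain
248,Uncertain
249,Uncertain
250,Uncertain
251,Uncertain
252,Uncertain
253,Uncertain
254,Uncertain
255,Uncertain
256,Uncertain
257,Uncertain
258,Uncertain
259,Uncertain
260,Uncertain
261,Uncertain
262,Uncertain
263,Uncertain
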