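parcel_id	network
1	Vis
2	Vis
3	Vis
4	Vis
5	Vis
6	Vis
7	Vis
8	Vis
9	Vis
10	Vis
11	Vis
12	Vis
13	Vis
14	Vis
15	Vis
16	Vis
17	Vis
18	Vis
19	Vis
20	Vis
21	Vis
22	Vis
23	Vis
24	Vis
25	Vis
26	Vis
27	Vis
28	Vis
29	Vis
30	SMN
31	SMN
32	SMN
33	SMN
34	SMN
35	SMN
36	SMN
37	SMN
38	SMN
39	SMN
40	SMN
41	SMN
42	SMN
43	SMN
44	SMN
45	SMN
46	SMN
47	SMN
48	SMN
49	SMN
50	SMN
51	SMN
52	SMN
53	SMN
54	SMN
55	SMN
56	SMN
57	SMN
58	SMN
59	SMN
60	SMN
61	SMN
62	SMN
63	SMN
64	SMN
65	DAN
66	DAN
67	DAN
68	DAN
69	DAN
70	DAN
71	DAN
72	DAN
73	DAN
74	DAN
75	DAN
76	DAN
77	DAN
78	DAN
79	DAN
80	DAN
81	DAN
82	DAN
83	DAN
84	DAN
85	DAN
86	DAN
87	DAN
88	DAN
89	DAN
90	DAN
91	VAN
92	VAN
93	VAN
94	VAN
95	VAN
96	VAN
97	VAN
98	VAN
99	VAN
100	VAN
101	VAN
102	VAN
103	VAN
104	VAN
105	VAN
106	VAN
107	VAN
108	VAN
109	VAN
110	VAN
111	VAN
112	VAN
113	VAN
114	VAN
115	VAN
116	VAN
117	Limbic
118	Limbic
119	Limbic
120	Limbic
121	Limbic
122	Limbic
123	Limbic
124	Limbic
125	Limbic
126	Limbic
127	Limbic
128	Limbic
129	FPN
130	FPN
131	FPN
132	FPN
133	FPN
134	FPN
135	FPN
136	FPN
137	FPN
138	FPN
139	FPN
140	FPN
141	FPN
142	FPN
143	FPN
144	FPN
145	FPN
146	FPN
147	FPN
148	FPN
149	FPN
150	FPN
151	FPN
152	FPN
153	FPN
154	FPN
155	DMN
156	DMN
157	DMN
158	DMN
159	DMN
160	DMN
161	DMN
162	DMN
163	DMN
164	DMN
165	DMN
166	DMN
167	DMN
168	DMN
169	DMN
170	DMN
171	DMN
172	DMN
173	DMN
174	DMN
175	DMN
176	DMN
177	DMN
178	DMN
179	DMN
180	DMN
181	DMN
182	DMN
183	DMN
184	DMN
185	DMN
186	DMN
187	DMN
188	DMN
189	DMN
190	DMN
191	DMN
192	DMN
193	DMN
194	DMN
195	DMN
196	DMN
197	DMN
198	DMN
199	DMN
200	DMN
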