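index	signal	statistic	axis
1	tAcc0g	mean	X
2	tAcc0g	mean	Y
3	tAcc0g	mean	Z
4	tAcc0g	sd	X
5	tAcc0g	sd	Y
6	tAcc0g	sd	Z
7	tAcc0g	mad	X
8	tAcc0g	mad	Y
9	tAcc0g	mad	Z
10	tAcc0g	max	X
11	tAcc0g	max	Y
12	tAcc0g	max	Z
13	tAcc0g	min	X
14	tAcc0g	min	Y
15	tAcc0g	min	Z
16	tAcc0g	energy	X
17	tAcc0g	energy	Y
18	tAcc0g	energy	Z
19	tAcc0g	iqr	X
20	tAcc0g	iqr	Y
21	tAcc0g	iqr	Z
22	tAcc0g	entropy	X
23	tAcc0g	entropy	Y
24	tAcc0g	entropy	Z
25	tAcc0g	sma	XYZ
26	tAcc0g	ar1	X
27	tAcc0g	ar2	X
28	tAcc0g	ar3	X
29	tAcc0g	ar4	X
30	tAcc0g	ar1	Y
31	tAcc0g	ar2	Y
32	tAcc0g	ar3	Y
33	tAcc0g	ar4	Y
34	tAcc0g	ar1	Z
35	tAcc0g	ar2	Z
36	tAcc0g	ar3	Z
37	tAcc0g	ar4	Z
38	tAcc0g	corr	XY
39	tAcc0g	corr	XZ
40	tAcc0g	corr	YZ
41	tGyro	mean	X
42	tGyro	mean	Y
43	tGyro	mean	Z
44	tGyro	sd	X
45	tGyro	sd	Y
46	tGyro	sd	Z
47	tGyro	mad	X
48	tGyro	mad	Y
49	tGyro	mad	Z
50	tGyro	max	X
51	tGyro	max	Y
52	tGyro	max	Z
53	tGyro	min	X
54	tGyro	min	Y
55	tGyro	min	Z
56	tGyro	energy	X
57	tGyro	energy	Y
58	tGyro	energy	Z
59	tGyro	iqr	X
60	tGyro	iqr	Y
61	tGyro	iqr	Z
62	tGyro	entropy	X
63	tGyro	entropy	Y
64	tGyro	entropy	Z
65	tGyro	sma	XYZ
66	tGyro	ar1	X
67	tGyro	ar2	X
68	tGyro	ar3	X
69	tGyro	ar4	X
70	tGyro	ar1	Y
71	tGyro	ar2	Y
72	tGyro	ar3	Y
73	tGyro	ar4	Y
74	tGyro	ar1	Z
75	tGyro	ar2	Z
76	tGyro	ar3	Z
77	tGyro	ar4	Z
78	tGyro	corr	XY
79	tGyro	corr	XZ
80	tGyro	corr	YZ
81	tAccJerk	mean	X
82	tAccJerk	mean	Y
83	tAccJerk	mean	Z
84	tAccJerk	sd	X
85	tAccJerk	sd	Y
86	tAccJerk	sd	Z
87	tAccJerk	mad	X
88	tAccJerk	mad	Y
89	tAccJerk	mad	Z
90	tAccJerk	max	X
91	tAccJerk	max	Y
92	tAccJerk	max	Z
93	tAccJerk	min	X
94	tAccJerk	min	Y
95	tAccJerk	min	Z
96	tAccJerk	energy	X
97	tAccJerk	energy	Y
98	tAccJerk	energy	Z
99	tAccJerk	iqr	X
100	tAccJerk	iqr	Y
101	tAccJerk	iqr	Z
102	tAccJerk	entropy	X
103	tAccJerk	entropy	Y
104	tAccJerk	entropy	Z
105	tAccJerk	sma	XYZ
106	tAccJerk	ar1	X
107	tAccJerk	ar2	X
108	tAccJerk	ar3	X
109	tAccJerk	ar4	X
110	tAccJerk	ar1	Y
111	tAccJerk	ar2	Y
112	tAccJerk	ar3	Y
113	tAccJerk	ar4	Y
114	tAccJerk	ar1	Z
115	tAccJerk	ar2	Z
116	tAccJerk	ar3	Z
117	tAccJerk	ar4	Z
118	tAccJerk	corr	XY
119	tAccJerk	corr	XZ
120	tAccJerk	corr	YZ
121	tGyroJerk	mean	X
122	tGyroJerk	mean	Y
123	tGyroJerk	mean	Z
124	tGyroJerk	sd	X
125	tGyroJerk	sd	Y
126	tGyroJerk	sd	Z
127	tGyroJerk	mad	X
128	tGyroJerk	mad	Y
129	tGyroJerk	mad	Z
130	tGyroJerk	max	X
131	tGyroJerk	max	Y
132	tGyroJerk	max	Z
133	tGyroJerk	min	X
134	tGyroJerk	min	Y
135	tGyroJerk	min	Z
136	tGyroJerk	energy	X
137	tGyroJerk	energy	Y
138	tGyroJerk	energy	Z
139	tGyroJerk	iqr	X
140	tGyroJerk	iqr	Y
141	tGyroJerk	iqr	Z
142	tGyroJerk	entropy	X
143	tGyroJerk	entropy	Y
144	tGyroJerk	entropy	Z
145	tGyroJerk	sma	XYZ
146	tGyroJerk	ar1	X
147	tGyroJerk	ar2	X
148	tGyroJerk	ar3	X
149	tGyroJerk	ar4	X
150	tGyroJerk	ar1	Y
151	tGyroJerk	ar2	Y
152	tGyroJerk	ar3	Y
153	tGyroJerk	ar4	Y
154	tGyroJerk	ar1	Z
155	tGyroJerk	ar2	Z
156	tGyroJerk	ar3	Z
157	tGyroJerk	ar4	Z
158	tGyroJerk	corr	XY
159	tGyroJerk	corr	XZ
160	tGyroJerk	corr	YZ
161	tAcc0gMag	mean	mag
162	tAcc0gMag	sd	mag
163	tAcc0gMag	mad	mag
164	tAcc0gMag	max	mag
165	tAcc0gMag	min	mag
166	tAcc0gMag	energy	mag
167	tAcc0gMag	iqr	mag
168	tAcc0gMag	entropy	mag
169	tAcc0gMag	sma	mag
170	tAcc0gMag	ar1	mag
171	tAcc0gMag	ar2	mag
172	tAcc0gMag	ar3	mag
173	tAcc0gMag	ar4	mag
174	tGyroMag	mean	mag
175	tGyroMag	sd	mag
176	tGyroMag	mad	mag
177	tGyroMag	max	mag
178	tGyroMag	min	mag
179	tGyroMag	energy	mag
180	tGyroMag	iqr	mag
181	tGyroMag	entropy	mag
182	tGyroMag	sma	mag
183	tGyroMag	ar1	mag
184	tGyroMag	ar2	mag
185	tGyroMag	ar3	mag
186	tGyroMag	ar4	mag
187	tAccJerkMag	mean	mag
188	tAccJerkMag	sd	mag
189	tAccJerkMag	mad	mag
190	tAccJerkMag	max	mag
191	tAccJerkMag	min	mag
192	tAccJerkMag	energy	mag
193	tAccJerkMag	iqr	mag
194	tAccJerkMag	entropy	mag
195	tAccJerkMag	sma	mag
196	tAccJerkMag	ar1	mag
197	tAccJerkMag	ar2	mag
198	tAccJerkMag	ar3	mag
199	tAccJerkMag	ar4	mag
200	tGyroJerkMag	mean	mag
201	tGyroJerkMag	sd	mag
202	tGyroJerkMag	mad	mag
203	tGyroJerkMag	max	mag
204	tGyroJerkMag	min	mag
205	tGyroJerkMag	energy	mag
206	tGyroJerkMag	iqr	mag
207	tGyroJerkMag	entropy	mag
208	tGyroJerkMag	sma	mag
209	tGyroJerkMag	ar1	mag
210	tGyroJerkMag	ar2	mag
211	tGyroJerkMag	ar3	mag
212	tGyroJerkMag	ar4	mag
213	fAcc0g	mean	X
214	fAcc0g	mean	Y
215	fAcc0g	mean	Z
216	fAcc0g	sd	X
217	fAcc0g	sd	Y
218	fAcc0g	sd	Z
219	fAcc0g	mad	X
220	fAcc0g	mad	Y
221	fAcc0g	mad	Z
222	fAcc0g	max	X
223	fAcc0g	max	Y
224	fAcc0g	max	Z
225	fAcc0g	min	X
226	fAcc0g	min	Y
227	fAcc0g	min	Z
228	fAcc0g	energy	X
229	fAcc0g	energy	Y
230	fAcc0g	energy	Z
231	fAcc0g	iqr	X
232	fAcc0g	iqr	Y
233	fAcc0g	iqr	Z
234	fAcc0g	entropy	X
235	fAcc0g	entropy	Y
236	fAcc0g	entropy	Z
237	fAcc0g	sma	XYZ
238	fAcc0g	maxInds	X
239	fAcc0g	maxInds	Y
240	fAcc0g	maxInds	Z
241	fAcc0g	meanFreq	X
242	fAcc0g	meanFreq	Y
243	fAcc0g	meanFreq	Z
244	fAcc0g	skewness	X
245	fAcc0g	skewness	Y
246	fAcc0g	skewness	Z
247	fAcc0g	kurtosis	X
248	fAcc0g	kurtosis	Y
249	fAcc0g	kurtosis	Z
250	fGyro	mean	X
251	fGyro	mean	Y
252	fGyro	mean	Z
253	fGyro	sd	X
254	fGyro	sd	Y
255	fGyro	sd	Z
256	fGyro	mad	X
257	fGyro	mad	Y
258	fGyro	mad	Z
259	fGyro	max	X
260	fGyro	max	Y
261	fGyro	max	Z
262	fGyro	min	X
263	fGyro	min	Y
264	fGyro	min	Z
265	fGyro	energy	X
266	fGyro	energy	Y
267	fGyro	energy	Z
268	fGyro	iqr	X
269	fGyro	iqr	Y
270	fGyro	iqr	Z
271	fGyro	entropy	X
272	fGyro	entropy	Y
273	fGyro	entropy	Z
274	fGyro	sma	XYZ
275	fGyro	maxInds	X
276	fGyro	maxInds	Y
277	fGyro	maxInds	Z
278	fGyro	meanFreq	X
279	fGyro	meanFreq	Y
280	fGyro	meanFreq	Z
281	fGyro	skewness	X
282	fGyro	skewness	Y
283	fGyro	skewness	Z
284	fGyro	kurtosis	X
285	fGyro	kurtosis	Y
286	fGyro	kurtosis	Z
287	fAccJerk	mean	X
288	fAccJerk	mean	Y
289	fAccJerk	mean	Z
290	fAccJerk	sd	X
291	fAccJerk	sd	Y
292	fAccJerk	sd	Z
293	fAccJerk	mad	X
294	fAccJerk	mad	Y
295	fAccJerk	mad	Z
296	fAccJerk	max	X
297	fAccJerk	max	Y
298	fAccJerk	max	Z
299	fAccJerk	min	X
300	fAccJerk	min	Y
301	fAccJerk	min	Z
302	fAccJerk	energy	X
303	fAccJerk	energy	Y
304	fAccJerk	energy	Z
305	fAccJerk	iqr	X
306	fAccJerk	iqr	Y
307	fAccJerk	iqr	Z
308	fAccJerk	entropy	X
309	fAccJerk	entropy	Y
310	fAccJerk	entropy	Z
311	fAccJerk	sma	XYZ
312	fAccJerk	maxInds	X
313	fAccJerk	maxInds	Y
314	fAccJerk	maxInds	Z
315	fAccJerk	meanFreq	X
316	fAccJerk	meanFreq	Y
317	fAccJerk	meanFreq	Z
318	fAccJerk	skewness	X
319	fAccJerk	skewness	Y
320	fAccJerk	skewness	Z
321	fAccJerk	kurtosis	X
322	fAccJerk	kurtosis	Y
323	fAccJerk	kurtosis	Z
324	fAcc0gMag	mean	mag
325	fAcc0gMag	sd	mag
326	fAcc0gMag	mad	mag
327	fAcc0gMag	max	mag
328	fAcc0gMag	min	mag
329	fAcc0gMag	energy	mag
330	fAcc0gMag	iqr	mag
331	fAcc0gMag	entropy	mag
332	fAcc0gMag	sma	mag
333	fAcc0gMag	maxInds	mag
334	fAcc0gMag	meanFreq	mag
335	fAcc0gMag	skewness	mag
336	fAcc0gMag	kurtosis	mag
337	fGyroMag	mean	mag
338	fGyroMag	sd	mag
339	fGyroMag	mad	mag
340	fGyroMag	max	mag
341	fGyroMag	min	mag
342	fGyroMag	energy	mag
343	fGyroMag	iqr	mag
344	fGyroMag	entropy	mag
345	fGyroMag	sma	mag
346	fGyroMag	maxInds	mag
347	fGyroMag	meanFreq	mag
348	fGyroMag	skewness	mag
349	fGyroMag	kurtosis	mag
350	fAccJerkMag	mean	mag
351	fAccJerkMag	sd	mag
352	fAccJerkMag	mad	mag
353	fAccJerkMag	max	mag
354	fAccJerkMag	min	mag
355	fAccJerkMag	energy	mag
356	fAccJerkMag	iqr	mag
357	fAccJerkMag	entropy	mag
358	fAccJerkMag	sma	mag
359	fAccJerkMag	maxInds	mag
360	fAccJerkMag	meanFreq	mag
361	fAccJerkMag	skewness	mag
362	fAccJerkMag	kurtosis	mag
363	fGyroJerkMag	mean	mag
364	fGyroJerkMag	sd	mag
365	fGyroJerkMag	mad	mag
366	fGyroJerkMag	max	mag
367	fGyroJerkMag	min	mag
368	fGyroJerkMag	energy	mag
369	fGyroJerkMag	iqr	mag
370	fGyroJerkMag	entropy	mag
371	fGyroJerkMag	sma	mag
372	fGyroJerkMag	maxInds	mag
373	fGyroJerkMag	meanFreq	mag
374	fGyroJerkMag	skewness	mag
375	fGyroJerkMag	kurtosis	mag
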