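time_ms,A,B
0,0,0
2,0,0
4,0,0
6,0,0
8,0,0
10,0,0
12,0,0
14,0,0
16,0,0
18,0,0
20,0,0
22,0,0
24,0,0
26,0,0
28,0,0
30,0,0
32,0,0
34,0,0
36,0,0
38,0,0
40,48,0
42,-48,0
44,48,0
46,-48,0
48,48,0
50,-48,0
52,48,0
54,-48,0
56,48,0
58,-48,0
60,48,0
62,-48,0
64,48,0
66,-48,0
68,48,0
70,-48,0
72,48,0
74,-48,0
76,48,0
78,-48,0
80,48,0
82,-48,0
84,48,0
86,-48,0
88,48,0
90,-48,0
92,48,0
94,-48,0
96,48,0
98,-48,0
100,48,0
102,-48,0
104,48,0
106,-48,0
108,48,0
110,48,0
112,48,0
114,48,0
116,48,0
118,48,0
120,48,0
122,48,0
124,48,0
126,48,0
128,48,0
130,48,0
132,48,0
134,48,0
136,-52,0
138,-52,0
140,-52,0
142,-52,0
144,-52,0
146,-52,0
148,-52,0
150,-52,0
152,-52,0
154,-52,0
156,-52,0
158,-52,0
160,48,0
162,-48,0
164,48,0
166,-48,0
168,48,0
170,-48,0
172,48,0
174,-48,0
176,48,0
178,-48,0
180,48,0
182,-48,0
184,48,0
186,-48,0
188,48,0
190,-48,0
192,48,0
194,-48,0
196,48,0
198,-48,0
200,48,0
202,-48,0
204,48,0
206,-48,0
208,48,0
210,-48,0
212,48,0
214,-48,0
216,48,0
218,-48,0
220,48,0
222,-48,0
224,48,0
226,-48,0
228,48,0
230,-48,0
232,48,0
234,-48,0
236,48,0
238,-48,0
240,48,0
242,-48,0
244,48,0
246,-48,0
248,48,0
250,-48,0
252,48,0
254,-48,0
256,48,0
258,-48,0
260,48,0
262,-48,0
264,48,0
266,-48,0
268,48,0
270,-48,0
272,48,0
274,-48,0
276,48,0
278,-48,0
280,48,0
282,-48,0
284,48,0
286,-48,0
288,48,0
290,-48,0
292,48,0
294,-48,0
296,48,0
298,-48,0
300,48,0
302,-48,0
304,48,0
306,-48,0
308,48,0
310,-48,0
312,48,0
314,-48,0
316,48,0
318,-48,0
320,48,0
322,0,0
324,0,0
326,0,0
328,0,0
330,0,0
332,0,0
334,0,0
336,0,0
338,0,0
340,0,0
342,0,0
344,0,0
346,0,0
348,0,0
350,0,0
352,0,0
354,0,0
356,0,0
358,0,0
360,0,0
362,0,0
364,0,0
366,0,0
368,0,0
370,0,0
372,0,0
374,0,0
376,0,0
378,0,0
380,0,0
382,0,0
384,0,0
386,0,0
388,0,0
390,0,0
392,0,0
394,0,0
396,0,0
398,0,0
400,0,0
402,0,0
404,0,0
406,0,0
408,0,0
410,0,0
412,0,0
414,0,0
416,0,0
418,0,0
420,0,0
422,0,0
424,0,0
426,0,0
428,0,0
430,0,0
432,0,0
434,0,0
436,0,0
438,0,0
440,0,0
442,0,0
444,0,0
446,0,0
448,0,0
450,0,0
452,0,0
454,0,0
456,0,0
458,0,0
460,0,0
462,0,0
464,0,0
466,0,0
468,0,0
470,0,0
472,0,0
474,0,0
476,0,0
478,0,0
480,0,0
482,0,0
484,0,0
486,0,0
488,0,0
490,0,0
492,0,0
494,0,0
496,0,0
498,0,0
500,0,0
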