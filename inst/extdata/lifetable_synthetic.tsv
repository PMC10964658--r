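age	sex	annual_death_probability
55	male	0.04102891181674517
56	male	0.041028911816745284
57	male	0.04102891181674584
58	male	0.04102891181674717
59	male	0.041028911816750724
60	male	0.041028911816760494
61	male	0.041028911816786695
62	male	0.04102891181685786
63	male	0.04102891181705026
64	male	0.041028911817570846
65	male	0.041028911818979275
66	male	0.041028911822790115
67	male	0.041028911833100534
68	male	0.04102891186099622
69	male	0.041028911936470625
70	male	0.04102891214067317
71	male	0.04102891269316178
72	male	0.04102891418796906
73	male	0.04102891823230437
74	male	0.04102892917461609
75	male	0.04102895878002111
76	male	0.041029038880094904
77	male	0.041029255597995085
78	male	0.04102984194746451
79	male	0.04103142836674356
80	male	0.04103572055322491
81	male	0.041047333352390414
82	male	0.04107875211707479
83	male	0.041163753242563494
84	male	0.041393693642025164
85	male	0.042015541628830366
86	male	0.043695985704099605
87	male	0.04822781584179592
88	male	0.060381721952807776
89	male	0.09249282552931914
90	male	0.1739774487304292
91	male	0.3596071417551925
92	male	0.6783704667266257
93	male	0.9500955138597011
94	male	0.9996773495862917
95	male	0.9999999996153247
96	male	1
97	male	1
98	male	1
99	male	1
100	male	1
101	male	1
102	male	1
103	male	1
104	male	1
105	male	1
106	male	1
107	male	1
108	male	1
109	male	1
110	male	1
55	female	0.04102891181674506
56	female	0.04102891181674517
57	female	0.041028911816745506
58	female	0.04102891181674617
59	female	0.04102891181674817
60	female	0.0410289118167535
61	female	0.04102891181676793
62	female	0.04102891181680712
63	female	0.04102891181691293
64	female	0.041028911817199254
65	female	0.04102891181797386
66	female	0.04102891182006985
67	female	0.04102891182574053
68	female	0.04102891184108315
69	female	0.041028911882594055
70	female	0.04102891199490555
71	female	0.041028912298774256
72	female	0.041028913120918276
73	female	0.04102891534530262
74	female	0.04102892136357417
75	female	0.04102893764654714
76	female	0.04102898170158953
77	female	0.041029100896447845
78	female	0.04102942338875237
79	female	0.041030295920061466
80	female	0.04103265662779132
81	female	0.04103904370514211
82	female	0.04105632430248829
83	female	0.04110307694741999
84	female	0.04122955899522163
85	female	0.0415716838928234
86	female	0.042496721621288036
87	female	0.044995021041105976
88	female	0.0517217659474295
89	female	0.0696850111685331
90	female	0.11659871112306597
91	female	0.23200561423589094
92	female	0.4741544082060043
93	female	0.8112924593401916
94	female	0.9882072469071065
95	female	0.9999934895003456
96	female	0.99999999999999
97	female	1
98	female	1
99	female	1
100	female	1
101	female	1
102	female	1
103	female	1
104	female	1
105	female	1
106	female	1
107	female	1
108	female	1
109	female	1
110	female	1
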