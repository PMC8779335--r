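molId	subclass	nominalMw	expAbundance	predAbundance	signedDiff	flag
5	Pyrimidines	126	82	32	-50	none
16	Pyrimidines	140	64	98	34	none
17	Pyrimidines	140	100	71	-29	none
19	Pyrimidines	141	100	91	-9	none
41	Pyrimidines	154	100	65	-35	none
42	Pyrimidines	154	80	57	-23	none
43	Pyrimidines	155	100	97	-3	none
81	Pyrimidines	170	100	41	-59	none
39	Xanthines	153	94	100	6	none
75	Xanthines	168	27	100	73	none
100	Xanthines	180	100	57	-43	none
106	Xanthines	181	25	67	42	none
132	Xanthines	195	14	49	35	none
28	Hypoxanthines	150	100	83	-17	none
31	Hypoxanthines	150	70	100	30	none
52	Hypoxanthines	164	100	57	-43	none
65	Lumazines	166	2	100	98	none
96	Lumazines	180	100	64	-36	none
121	Lumazines	192	100	79	-21	none
128	Lumazines	194	100	87	-13	none
86	Quinazolinediones	177	60	26	-34	none
115	Quinazolinediones	190	100	87	-13	none
120	Quinazolinediones	192	100	88	-12	none
92	Remycins	179	66	19	-47	none
105	Remycins	181	1	49	48	none
123	Remycins	193	24	40	16	none
125	Remycins	193	63	27	-36	none
126	Remycins	193	100	31	-69	none
147	Remycins	207	14	23	9	none
47	Pyridopyrimidinediones	163	100	82	-18	none
50	Pyridopyrimidinediones	163	88	100	12	none
116	Pyridopyrimidinediones	191	100	84	-16	none
117	Pyridopyrimidinediones	191	100	54	-46	none
118	Pyridopyrimidinediones	191	100	90	-10	none
70	Others	167	11	89	78	none
74	Others	168	100	59	-41	none
80	Others	170	100	21	-79	none
122	Others	192	49	100	-51	sign_inconsistent
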