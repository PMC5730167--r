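species	group	exon1	exon2	exon3	exon4	exon5	exon6	exon7	exon8	exon9	exon10	exon11	exon12	exon13	exon14	exon15	exon16	intron1	intron2	intron3	intron4	intron5	intron6	intron7	intron8	intron9	intron10	intron11	intron12	intron13	intron14	intron15
maize	monocot	99	70	2901	217	276	182	115	111	104	173	136	186	135	114	127	136	666	78	177	464	645	113	404	1466	408	133	399	125	99	103	111
rice	monocot	87	70	1542	216	273	180	115	111	105	173	131	186	134	114	129	136	439	81	299	169	567	64	418	381	352	136	236	104	92	81	76
barley	monocot	90	70	2661	220	273	181	115	119	104	173	134	186	134	114	133	136	926	82	196	344	858	106	249	660	310	91	79	115	98	89	73
sorghum	monocot	96	69	2931	217	276	182	112	110	104	174	136	186	135	128	127	136	464	80	210	465	634	115	402	920	467	126	311	141	83	130	97
wheat	monocot	85	67	2664	220	273	181	115	119	104	173	134	186	132	114	133	133	985	470	259	362	777	115	251	901	269	133	89	118	795	92	82
brachypodium	monocot	96	70	2940	216	273	181	114	119	104	174	131	186	134	114	141	136	2066	77	290	753	518	113	503	933	128	133	77	112	117	103	76
soybean	dicot	60	56	1367	217	273	178	112	110	108	173	132	185	138	120	130	138	2058	113	727	313	772	227	407	857	343	114	609	553	90	188	892
arabidopsis	dicot	117	64	1136	220	279	179	112	113	208	173	133	185	135	114	127	132	631	74	115	124	78	75	86	94	106	116	82	73	92	92	80
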