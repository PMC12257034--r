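identity	length	mismatches	gap_opens	q_start	q_end	s_start	s_end	genes_cp	genes_mt
99.342	9572	8	7	133762	143315	796675	787141	rps12;rrn4.5;rrn23;trnA-UGC;orf42;trnI-GAU;rrn16;trnV-GAC	trnV-GAC;trnI-GAT;trnA-TGC
99.342	9572	8	7	100337	109890	787141	796675	rps12;trnV-GAC;rrn16;trnI-GAU;trnA-UGC;orf42;rrn23;rrn4.5	trnV-GAC;trnI-GAT;trnA-TGC
99.467	1689	1	1	155251	156939	249545	247865	rpl23;rpl2
99.467	1689	1	1	86713	88401	247865	249545	rpl2;rpl23
87.169	982	82	19	66276	67217	866044	865067	psbJ;psbL;psbF;psbE
85.504	1021	85	32	68281	69295	864681	863718	petL;petG;trnW-CCA;trnP-UGG	trnW-CCA;trnW-CCA
81.926	758	99	19	51363	52105	779260	779994	ndhJ;ndhK
86.337	505	38	9	54541	55027	368120	368611	atpE;atpB
81.971	416	41	18	25898	26287	871628	871221	rpoB
74.045	890	174	42	139520	140383	245971	245113	rrn16	rrn18
74.045	890	174	42	103269	104132	245113	245971	rrn16	rrn18
95.918	147	6	0	36637	36783	340240	340386	psbC
91.275	149	13	0	31883	32031	709660	709808	trnD-GUC	trnD-GTC
92.913	127	9	0	154860	154986	660602	660476	trnI-CAU	trnM-CAT
92.913	127	9	0	88666	88792	660476	660602	trnI-CAU	trnM-CAT
88.889	126	8	2	149246	149371	517689	517570	ycf2
88.889	126	8	2	94281	94406	517570	517689	ycf2
90.517	116	4	1	108480	108595	654611	654503	rrn23
90.517	116	4	1	135057	135172	654503	654611	rrn23
96.429	84	2	1	132349	132431	327451	327368	trnN-GUU	trnN-GTT
96.429	84	2	1	111221	111303	327368	327451	trnN-GUU	trnN-GTT
97.368	76	2	0	88717	88792	750548	750473	trnI-CAU	ccmC;trnM-CAT
97.368	76	2	0	154860	154935	750473	750548	trnI-CAU	ccmC;trnM-CAT
93.506	77	5	0	54227	54303	337154	337230	trnM-CAU	trnM-CAT
100	42	0	0	122881	122922	787772	787813	ndhA
90.566	53	5	0	150673	150725	590443	590391	ycf2
90.566	53	5	0	92927	92979	590391	590443	ycf2
90.385	52	1	3	155041	155092	80066	80019
90.385	52	1	3	88560	88611	80019	80066
97.297	37	0	1	144192	144228	100452	100417
97.297	37	0	1	99424	99460	100417	100452
97.059	34	1	0	76213	76246	84470	84437	psbB
97.059	34	1	0	76213	76246	430900	430867	psbB
96.875	32	1	0	31989	32020	598206	598175	trnD-GUC
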