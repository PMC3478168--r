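region	class	pct_cpg	pct_gc	loci	divergence_pct	se_pct	compared_kb	ts_tv
utr5	all	7.33	37.36	210	3.35	0.21	22.11	1.47
utr5	non_cpg	7.33	37.36	210	3.05	0.21	20.49	1.34
utr5	cpg	7.33	37.36	210	8.28	1.03	1.62	2.38
cds	all	7.13	43.44	2966	1.73	0.02	1434.41	2.94
cds	non_cpg	7.13	43.44	2966	1.29	0.02	1332.11	2.53
cds	cpg	7.13	43.44	2966	7.77	0.12	102.30	4.17
cds	nd_all	6.27	44.17	2966	0.47	0.02	840.49	1.43
cds	nd_noncpg	6.27	44.17	2966	0.42	0.02	787.78	1.29
cds	nd_cpg	6.27	44.17	2966	1.27	0.07	52.71	2.41
cds	fourd_all	12.07	37.64	2966	5.30	0.07	200.59	2.18
cds	fourd_noncpg	12.07	37.64	2966	3.43	0.06	176.37	1.55
cds	fourd_cpg	12.07	37.64	2966	20.11	0.36	24.22	3.52
utr3	all	4.68	35.74	337	2.91	0.16	46.95	2.01
utr3	non_cpg	4.68	35.74	337	2.52	0.15	44.75	1.68
utr3	cpg	4.68	35.74	337	12.42	0.97	2.20	4.48
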