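classifier	variant	f1	mcc	iauc	rank_f1	rank_mcc	rank_iauc	rp3	typo_cells
LDA	BICEPP	0.933	0.737	0.985	2	1	1	2	
LDA	i-Drugs	0.934	0.736	0.985	1	2	1	2	
Log Reg	BICEPP	0.933	0.714	0.985	2	3	1	8	rank_mcc
Log Reg	i-Drugs	0.930	0.700	0.985	6	6	1	36	
LDA	-	0.931	0.728	0.984	5	3	5	75	
SVM	BICEPP	0.932	0.710	0.984	4	5	5	100	
Log Reg	-	0.929	0.698	0.984	8	7	5	280	
SVM	i-Drugs	0.930	0.687	0.984	6	10	5	300	
SVM	-	0.928	0.693	0.983	9	8	9	648	
VTT	BICEPP	0.922	0.692	0.980	11	9	12	1188	
VTT	OSCAR4	0.923	0.683	0.979	10	11	14	1540	
VTT	i-Drugs	0.920	0.670	0.981	12	14	10	1680	
Naive Bayes	-	0.920	0.661	0.981	12	16	10	1920	
dLDA	BICEPP	0.911	0.680	0.976	15	12	15	2700	
VTT	-	0.919	0.656	0.980	14	17	12	2856	
dLDA	i-Drugs	0.911	0.678	0.975	15	13	16	2700	rp3
dLDA	-	0.909	0.670	0.975	17	14	16	3808	
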