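classifier	variant	f1	mcc	iauc	rank_f1	rank_mcc	rank_iauc	rp3	typo_cells
LDA	BICEPP	0.757	0.650	0.831	1	1	1	1	
SVM	BICEPP	0.741	0.639	0.831	4	3	1	12	
LDA	-	0.752	0.642	0.826	2	2	4	16	
Log Reg	BICEPP	0.738	0.634	0.828	5	4	3	60	
VTT	BICEPP	0.742	0.629	0.805	3	7	7	147	
SVM	-	0.736	0.633	0.824	6	5	5	150	
Log Reg	-	0.734	0.630	0.823	8	6	6	288	
VTT	-	0.736	0.617	0.797	6	8	8	432	rank_mcc
Naive Bayes	-	0.734	0.619	0.796	8	8	10	640	
dLDA	BICEPP	0.711	0.603	0.797	10	10	8	800	
dLDA	-	0.710	0.600	0.794	11	11	11	1331	
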