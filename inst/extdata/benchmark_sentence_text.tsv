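classifier	variant	f1	mcc	iauc	rank_f1	rank_mcc	rank_iauc	rp3
LDA	Bigram	0.752	0.642	0.826	1	1	1	1
LDA	Unigram	0.750	0.636	0.819	2	2	4	16
SVM	Bigram	0.736	0.633	0.824	3	3	2	18
Log Reg	Bigram	0.734	0.630	0.823	7	4	3	84
SVM	Unigram	0.735	0.630	0.819	6	4	4	96
VTT	Bigram	0.736	0.617	0.797	3	8	7	168
Naive Bayes	Unigram	0.736	0.617	0.791	3	8	10	240
Log Reg	Unigram	0.734	0.629	0.818	7	6	6	252
Naive Bayes	Bigram	0.734	0.619	0.796	7	7	8	392
dLDA	Unigram	0.732	0.613	0.790	11	10	11	1210
dLDA	Bigram	0.710	0.600	0.794	12	12	9	1296
VTT	Unigram	0.733	0.606	0.789	10	11	12	1320
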