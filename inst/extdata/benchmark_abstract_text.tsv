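classifier	variant	f1	mcc	iauc	rank_f1	rank_mcc	rank_iauc	rp3
LDA	Bigram	0.931	0.728	0.984	1	1	1	1
Log Reg	Bigram	0.929	0.698	0.984	2	3	1	6
SVM	Bigram	0.928	0.693	0.983	3	4	3	36
LDA	Unigram	0.926	0.719	0.983	6	2	3	36
Log Reg	Unigram	0.927	0.689	0.980	4	5	6	120
SVM	Unigram	0.927	0.689	0.980	4	5	6	120
Naive Bayes	Bigram	0.920	0.661	0.981	7	10	5	350
Naive Bayes	Unigram	0.919	0.672	0.978	8	7	9	504
VTT	Bigram	0.919	0.656	0.980	8	12	6	576
VTT	Unigram	0.918	0.662	0.977	10	9	10	900
dLDA	Bigram	0.909	0.670	0.975	11	8	11	968
dLDA	Unigram	0.908	0.658	0.974	12	11	12	1584
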