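domain	site	start	length	expected_malonyl	expected_methylmalonyl	note
KS	ks_cys	23	1	NA	NA	triad Cys; Gln in loading KSq
KS	ks_his1	47	1	NA	NA	triad His
KS	ks_his2	75	1	NA	NA	triad His/Asn
KS	ks_cys_motif	20	7	NA	NA	DTAxSSS anchor
KS	ks_his1_motif	45	7	NA	NA	SAxGTGT anchor
KS	ks_his2_motif	70	7	NA	NA	KSNIGxL anchor
AT	at_ser_motif	30	5	NA	NA	GHSQG active site
AT	at_diag1	10	1	H	Y	specificity column (synthetic)
AT	at_diag2	18	1	A	S	specificity column (synthetic)
AT	at_diag3	50	1	F	M	specificity column (synthetic)
AT	at_diag4	62	1	T	G	specificity column (synthetic)
DH	dh_motif	25	9	NA	NA	HxxxGxxxP consensus
ER	er_motif	25	17	NA	NA	LxHxxxGGVGxxAxxxA consensus
KR	kr_nadph_motif	10	7	NA	NA	GxTGxLG NADP(H) binding
KR	kr_b_window	40	3	NA	NA	B-type LDD/LED window
KR	kr_a_site	55	1	NA	NA	A-type Trp site
KR	kr_triad	70	3	NA	NA	KSY catalytic triad
ACP	acp_motif	15	5	NA	NA	L/IG(x)DS
ACP	acp_ser	19	1	NA	NA	essential phosphopantetheine Ser
TE	te_motif	20	6	NA	NA	GWSxGG active site
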