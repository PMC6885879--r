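snp_id	effect_allele	other_allele	maf	beta_x	se_x	pval_x	unit	source
rs10936599	C	T	0.27	0.117	0.009	2.5e-31	kb	synthetic: approximate literature value, TERC region
rs2736100	C	A	0.41	0.078	0.009	4.4e-19	kb	synthetic: approximate literature value, TERT region
rs7675998	G	A	0.22	0.074	0.011	4.3e-16	kb	synthetic: approximate literature value, NAF1 region
rs4387287	A	C	0.12	0.072	0.012	3.9e-10	kb	synthetic: approximate literature value, OBFC1 region
rs8105767	G	A	0.28	0.048	0.008	1.1e-9	kb	synthetic: approximate literature value, ZNF208 region
rs755017	G	A	0.25	0.062	0.011	6.7e-9	kb	synthetic: approximate literature value, RTEL1 region
rs11125529	C	A	0.13	0.065	0.012	4.5e-8	kb	synthetic: approximate literature value, ACYP2 region
rs3027234	T	C	0.20	0.042	0.009	2.9e-8	kb	synthetic: approximate literature value, CTC1 region
rs412658	T	C	0.36	0.070	0.011	3.5e-8	kb	synthetic: approximate literature value, ZNF676 region
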