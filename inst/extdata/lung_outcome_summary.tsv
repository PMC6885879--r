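snp_id	stratum	or_value	ci_low	ci_high	pval	n
rs10936599	overall	1.10	1.04	1.15	2.51e-4	13945
rs2736100	overall	1.33	1.26	1.39	5.05e-29	13945
rs7675998	overall	1.07	1.00	1.14	0.052	13945
rs4387287	overall	0.99	0.93	1.06	0.795	13945
rs8105767	overall	1.02	0.97	1.08	0.385	13945
rs755017	overall	0.97	0.93	1.02	0.297	13945
rs11125529	overall	1.05	0.99	1.12	0.120	13945
rs3027234	overall	1.05	0.92	1.18	0.482	13945
rs412658	overall	1.03	0.97	1.08	0.331	13945
rs10936599	adenocarcinoma	1.12	1.06	1.19	2.42e-5	11591
rs2736100	adenocarcinoma	1.37	1.30	1.45	5.17e-30	11591
rs7675998	adenocarcinoma	1.06	0.98	1.14	0.126	11591
rs4387287	adenocarcinoma	0.99	0.92	1.06	0.708	11591
rs8105767	adenocarcinoma	1.05	0.99	1.11	0.131	11591
rs755017	adenocarcinoma	0.99	0.94	1.05	0.809	11591
rs11125529	adenocarcinoma	1.05	0.98	1.13	0.157	11591
rs3027234	adenocarcinoma	1.07	0.93	1.23	0.368	11591
rs412658	adenocarcinoma	1.03	0.97	1.09	0.367	11591
rs10936599	squamous	1.05	0.96	1.14	0.300	8300
rs2736100	squamous	1.21	1.11	1.32	1.25e-5	8300
rs7675998	squamous	1.13	1.01	1.27	0.034	8300
rs4387287	squamous	0.98	0.87	1.10	0.694	8300
rs8105767	squamous	0.97	0.89	1.06	0.523	8300
rs755017	squamous	0.89	0.82	0.97	8.44e-3	8300
rs11125529	squamous	1.06	0.95	1.18	0.317	8300
rs3027234	squamous	1.04	0.83	1.30	0.729	8300
rs412658	squamous	0.99	0.91	1.08	0.809	8300
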