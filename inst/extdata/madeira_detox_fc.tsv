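class	accession	gene	fc.FunchalVsRockefeller	p.FunchalVsRockefeller	fc.FunchalVsNewOrleans	p.FunchalVsNewOrleans	fc.PaulDoMarVsRockefeller	p.PaulDoMarVsRockefeller
P450	AAEL008846	Cyp9J32	41	0.006	53	0.004	10	0.060
P450	AAEL014617	Cyp9J28	31	0.028	30	0.019	10	0.008
P450	AAEL014893	Cyp6BB2	15	0.005	19	0.0007	3.6	0.006
P450	AAEL014607	Cyp9J27	14	0.021	18	0.018	3.5	0.023
P450	AAEL014616	Cyp9J27	14	0.020	16	0.016	4.6	0.006
P450	AAEL001288	Cyp9M5	6.6	0.0006	8.5	0.009	2.3	0.001
P450	AAEL001312	Cyp9M6	5.4	0.015	4.7	0.006	4	0.031
P450	AAEL009124	Cyp6N12	5.1	0.0003	6.3	0.003	2.2	0.002
P450	AAEL017297	Cyp6M9	4.2	0.007	3.7	0.001	3	0.047
Esterase	AAEL005112	CCEae3a	2.7	0.009	3.4	0.012	2.1	0.001
GST	AAEL001054	GSTd4	24	0.0004	22	0.0002	9.8	0.004
GST	AAEL011741	GSTs1	4.9	0.0002	2.5	0.00007	2.2	0.032
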