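rsid	nearest_gene	chrom	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs12134663	MTHFR	1	C	A	0.2	0.101	0.011	2.54e-21	44147
rs12780845	CUBN	10	A	G	0.65	0.0529	0.009	7.8e-10	44147
rs1801222	CUBN	10	A	G	0.34	0.0453	0.007	8.43e-10	44147
rs2275565	MTR	1	G	T	0.79	0.0542	0.009	1.96e-10	44147
rs234709	CBS	21	C	T	0.55	0.0718	0.007	3.9e-24	44147
rs42648	GTPB10	7	G	A	0.6	0.0395	0.007	1.97e-08	44147
rs4660306	MMACHC	1	T	C	0.33	0.0435	0.007	2.33e-09	44147
rs7130284	NOX4	11	C	T	0.93	0.1242	0.013	1.88e-20	44147
rs838133	FUT2	19	A	G	0.45	0.0422	0.007	7.48e-09	44147
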