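rsid	nearest_gene	chrom	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs12134663	MTHFR	1	C	A	NA	0.0109	0.0089	0.22	1030836
rs12780845	CUBN	10	A	G	NA	-0.0013	0.0071	0.85	1030836
rs1801222	CUBN	10	A	G	NA	0.0069	0.0069	0.32	1030836
rs2275565	MTR	1	G	T	NA	0.0002	0.0081	0.98	1030836
rs234709	CBS	21	C	T	NA	0.0079	0.0072	0.27	1030836
rs42648	GTPB10	7	G	A	NA	-0.0015	0.0068	0.82	1030836
rs4660306	MMACHC	1	T	C	NA	0.0047	0.007	0.50	1030836
rs7130284	NOX4	11	C	T	NA	0.0035	0.0123	0.78	1030836
rs838133	FUT2	19	A	G	NA	0.0085	0.0072	0.24	1030836
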