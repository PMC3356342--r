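gene_id	symbol	sample_id	sense	antisense	sense_uq	antisense_uq
cut01g0000110	CuAdh1-F	log	NA	NA	134.37	0.88
cut01g0000110	CuAdh1-F	stationary	145562	226551	23.92	81.83
cut01g0050119	CuAdh2	log	NA	NA	8.56	0.31
cut01g0050119	CuAdh2	stationary	NA	NA	26.35	5.66
cut01g0021005	CuAdh3	log	NA	NA	12.63	0.94
cut01g0021005	CuAdh3	stationary	NA	NA	68.16	5.41
cut01g0020374	CuAld6-c	log	NA	NA	7.93	0
cut01g0020374	CuAld6-c	stationary	NA	NA	8.08	0
cut01g0030970	CuAld5	log	NA	NA	2.40	0.52
cut01g0030970	CuAld5	stationary	NA	NA	0.22	0.071
cut01g0050658	CuAld6-m	log	NA	NA	9.10	0.52
cut01g0050658	CuAld6-m	stationary	NA	NA	62.11	0.33
cut01g0001347	CuHxt6	log	NA	NA	52.84	0
cut01g0001347	CuHxt6	stationary	NA	NA	39.93	0
cut01g0020536	CuHxt10	log	NA	NA	0.17	0
cut01g0020536	CuHxt10	stationary	NA	NA	0.16	0
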