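family	motif	location	prevalence
lysine	AGAGGUGC	10	NA
lysine	AGUAA	28	NA
cobalamin	CGGUG	18	NA
cobalamin	GCA	77	NA
cobalamin	AGC	92	NA
cobalamin	AGA	175	NA
cobalamin	GACC	180	NA
glycine	GGAGA	13	NA
glycine	CCGA	35	NA
SAM-alpha	GUGGU	11	NA
SAM-alpha	AUUUG	17	NA
SAM-alpha	GCCACGU	37	NA
SAM-IV	UCA	3	NA
SAM-IV	GAG	7	NA
SAM-IV	CAG	13	NA
SAM-IV	GCUGG	32	NA
SAM-IV	CGGCAACC	38	NA
cyclic-di-GMP-I	GAAA	23	NA
cyclic-di-GMP-I	CGCAAAGC	35	NA
SAH	GAGGAGCG	7	NA
SAH	UGC	16	NA
SAH	AGGCUCGG	36	NA
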