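set	pct_a	pct_c	pct_g	pct_t	total_bases
genome	29.97	20.04	20.04	29.96	1359400017
refseq_sisrnas	29.09	20.92	21.00	28.99	9027876
ensembl_sisrnas	29.14	20.88	20.91	29.07	12146831
introns_without_sisrnas	30.32	19.66	19.67	30.36	117363589
introns_with_sisrnas	29.74	20.27	20.32	29.67	105176094
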