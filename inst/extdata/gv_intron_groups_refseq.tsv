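intron_count_group	n_genes	n_total_introns	n_genes_with_sisrna	n_sisrnas
0	584	0	NA	NA
1	583	583	145	347
2	729	1458	341	743
3	812	2436	471	1254
4	777	3108	488	1564
5	716	3580	477	1472
6	683	4098	486	1677
7	599	4193	420	1450
8	580	4640	408	1621
9	506	4554	397	1575
>=10	2879	45110	2332	14581
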