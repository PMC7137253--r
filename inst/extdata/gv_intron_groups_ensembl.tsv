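intron_count_group	n_genes	n_total_introns	n_genes_with_sisrna	n_sisrnas
0	2654	0	NA	NA
1	3600	3600	415	911
2	2461	4922	648	1383
3	1986	5958	807	1951
4	1791	7164	847	2140
5	1696	8480	919	2439
6	1543	9258	826	2431
7	1458	10206	835	2613
8	1372	10976	772	2637
9	1260	11340	767	2687
>=10	9146	162302	6208	31887
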