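dataset	n	total_length	min_length	median_length	max_length	genome_size
all_peaks	63410	21899763	160	271	2908	1513925492
ensembl_sisrnas	34169	12184476	160	283	2908	1513925492
refseq_sisrnas	24901	9054977	160	288	2908	1513925492
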