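#!/usr/bin/env Rscript
# Distribution of sisRNAs over genes: intron-count group table, length
# correlations, and the signal-versus-expression coupling.

suppressPackageStartupMessages({
  library(sisprofiler)
  library(GenomicRanges)
})
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/bundle/genome.fa")
genes <- load_gene_models("scratch/bundle/genes.genePred", "genepred")
peaks <- read_peaks("scratch/bundle/peaks.bed")
fpkm <- read_fpkm("scratch/bundle/fpkm.tsv")
introns <- classify_intron_position(derive_introns(genes))
sis <- suppressWarnings(classify_peaks(peaks, genes, introns = introns))

counts <- count_per_gene(sis, genes)
groups <- group_by_intron_count(counts)
write.table(groups, "results/intron_group_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
total <- groups[groups$intron_count_group == "Total", ]
message("overall: ", round(total$pct_genes_with_sisrna, 1),
        "% of intron-containing genes host sisRNAs (",
        round(total$sisrnas_per_gene, 2), " per gene, ",
        round(total$sisrnas_per_intron, 2), " per intron)")

# per-intron and per-gene covariates
per_intron_n <- vapply(seq_along(introns), function(i)
  sum(sis$host_gene_id == introns$gene_id[i] &
        sis$host_intron_ordinal == introns$ordinal[i]), integer(1))
r_intron_len <- correlate(width(introns), per_intron_n)
total_intron_len <- tapply(width(introns), introns$gene_id, sum)
gene_counts <- counts$n_sisrnas[match(names(total_intron_len),
                                      counts$gene_id)]
n_introns <- counts$n_introns[match(names(total_intron_len), counts$gene_id)]
r_total_len <- correlate(as.numeric(total_intron_len), gene_counts)
r_n_introns <- correlate(n_introns, gene_counts)
coupling <- correlate_signal_expression(sis, fpkm)

cors <- data.frame(
  comparison = c("intron_length_vs_sisrna_count",
                 "total_intron_length_vs_sisrna_count_per_gene",
                 "n_introns_vs_sisrna_count_per_gene",
                 "peak_signal_vs_host_fpkm"),
  pearson_r = c(r_intron_len, r_total_len, r_n_introns, coupling$r),
  n = c(length(introns), length(total_intron_len), length(n_introns),
        coupling$n_pairs))
write.table(cors, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("longer introns host more sisRNAs (R = ", round(r_intron_len, 2),
        "); total intron length per gene R = ", round(r_total_len, 2),
        "; signal vs FPKM R = ", round(coupling$r, 2))
message("wrote results/intron_group_table.tsv, results/correlations.tsv")
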