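#!/usr/bin/env Rscript
# Motif enrichment: scan the whole genome with the bundle's PWMs (planted
# motif plus a never-planted control), then score enrichment E =
# OCC_obs / (N * L_r / L_g) in sisRNAs and in introns without sisRNAs.

suppressPackageStartupMessages({
  library(sisprofiler)
  library(GenomicRanges)
})
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/bundle/genome.fa")
genes <- load_gene_models("scratch/bundle/genes.genePred", "genepred")
peaks <- read_peaks("scratch/bundle/peaks.bed")
pwms <- read_transfac("scratch/bundle/motifs.transfac")
introns <- derive_introns(genes)
sis <- unique_sisrnas(suppressWarnings(classify_peaks(peaks, genes,
                                                      introns = introns)))
no_sis <- introns[countOverlaps(introns, sis, ignore.strand = TRUE) == 0]

message("scanning ", round(genome_length(genome) / 1e6, 1), " Mb with ",
        length(pwms), " PWMs (p_site = 1e-4) ...")
occ <- scan_genome(pwms, genome, p_site = 1e-4)
message(length(occ), " occurrences found")

enr_sis <- motif_enrichment(occ, sis, genome)
enr_nosis <- motif_enrichment(occ, no_sis, genome)
tab <- merge(enr_sis, enr_nosis, by = "motif_id",
             suffixes = c("_sisrnas", "_introns_no_sisrna"))
write.table(tab, "results/motif_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(enr_sis)))
  message(enr_sis$motif_id[i], ": N = ", enr_sis$n_genome[i],
          ", E in sisRNAs = ", round(enr_sis$enrichment[i], 2),
          ", E in sisRNA-free introns = ",
          round(enr_nosis$enrichment[enr_nosis$motif_id ==
                                       enr_sis$motif_id[i]], 2))

# robustness: E computed on the classified set versus on the planted truth
truth <- read.table("scratch/bundle/truth_sisrnas.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
truth_gr <- GRanges(truth$scaffold,
                    IRanges(truth$start + 1L, truth$end))
scatter <- enrichment_scatter(enr_sis, motif_enrichment(occ, truth_gr, genome))
write.table(scatter$table, "results/motif_enrichment_scatter.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/motif_enrichment.tsv")
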