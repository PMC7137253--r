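#!/usr/bin/env Rscript
# Classify the peak calls of the simulated bundle into sisRNAs from the files
# on disk (exercising the FASTA/genePred/BED loaders), and compare against
# the planted truth.

suppressPackageStartupMessages({
  library(sisprofiler)
  library(GenomicRanges)
})
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/bundle/genome.fa")
genes <- load_gene_models("scratch/bundle/genes.genePred", "genepred",
                          genome = genome)
peaks <- read_peaks("scratch/bundle/peaks.bed")
message("loaded ", length(genome), " scaffolds, ", length(genes),
        " genes, ", length(peaks), " peaks")

sis <- suppressWarnings(classify_peaks(peaks, genes))
usis <- unique_sisrnas(sis)
message(length(usis), " peaks accepted as sisRNAs (",
        length(sis), " host assignments)")

truth <- read.table("scratch/bundle/truth_sisrnas.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
got <- paste(as.character(seqnames(usis)), start(usis) - 1L, end(usis))
want <- paste(truth$scaffold, truth$start, truth$end)
message("recovery: ", length(intersect(got, want)), "/", nrow(truth),
        " planted sisRNAs, ", length(setdiff(got, want)), " false calls")

calls <- data.frame(
  scaffold = as.character(seqnames(sis)),
  start = start(sis) - 1L, end = end(sis),
  peak_id = sis$peak_id, signal = sis$signal, fdr = sis$fdr,
  host_gene_id = sis$host_gene_id,
  host_intron_ordinal = sis$host_intron_ordinal)
write.table(calls, "results/sisrna_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- summarize_dataset(sis, genome)
write.table(summ, "results/sisrna_dataset_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean sisRNA length ", round(summ$mean_length, 1), " bp; ",
        round(summ$pct_of_genome, 2), "% of the genome")
message("wrote results/sisrna_calls.tsv, results/sisrna_dataset_summary.tsv")
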