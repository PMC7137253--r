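#!/usr/bin/env Rscript
# Sequence composition of sisRNAs versus the genome and versus intron
# categories: GC%, CpG and CA|TG density, and reverse-complement-collapsed
# dinucleotide / trinucleotide O/E ratios.

suppressPackageStartupMessages({
  library(sisprofiler)
  library(GenomicRanges)
})
dir.create("results", showWarnings = FALSE)

genome <- load_genome("scratch/bundle/genome.fa")
genes <- load_gene_models("scratch/bundle/genes.genePred", "genepred")
peaks <- read_peaks("scratch/bundle/peaks.bed")
introns <- derive_introns(genes)
sis <- unique_sisrnas(suppressWarnings(classify_peaks(peaks, genes,
                                                      introns = introns)))
with_sis <- countOverlaps(introns, sis, ignore.strand = TRUE) > 0

region_sets <- list(
  genome = whole_genome_regions(genome),
  sisrnas = granges(sis),
  introns_with_sisrnas = granges(introns[with_sis]),
  introns_without_sisrnas = granges(introns[!with_sis]))

profiles <- lapply(names(region_sets), function(nm) {
  p <- composition_profile(region_sets[[nm]], genome, nm)
  data.frame(set = nm, total_bases = p$total_bases,
             pct_a = 100 * p$base_fractions[["A"]],
             pct_c = 100 * p$base_fractions[["C"]],
             pct_g = 100 * p$base_fractions[["G"]],
             pct_t = 100 * p$base_fractions[["T"]],
             gc_pct = 100 * p$gc_fraction,
             cpg_per_100bp = p$cpg_density,
             catg_per_100bp = p$catg_density)
})
comp <- do.call(rbind, profiles)
write.table(comp, "results/composition_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("GC%: genome ", round(comp$gc_pct[1], 2), ", sisRNAs ",
        round(comp$gc_pct[2], 2), "; CpG density ",
        round(comp$cpg_per_100bp[1], 2), " vs ",
        round(comp$cpg_per_100bp[2], 2), " per 100 bp")

for (k in c(2L, 3L)) {
  oe <- kmer_oe(sis, genome, k)
  oe <- oe[order(-oe$oe), ]
  write.table(oe, sprintf("results/kmer_oe_k%d_sisrnas.tsv", k), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("k=", k, ": most enriched class in sisRNAs ",
          oe$representative[1], " (O/E ", round(oe$oe[1], 2),
          "), most depleted ", tail(oe$representative, 1), " (O/E ",
          round(tail(oe$oe, 1), 2), ")")
}

# per-region distributions for boxplot-style comparison
cmp <- compare_sets(list(
  sisrnas = per_region_composition(sis, genome),
  introns_with_sisrnas = per_region_composition(introns[with_sis], genome),
  introns_without_sisrnas = per_region_composition(introns[!with_sis],
                                                   genome)))
write.table(cmp$summary, "results/composition_per_region_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/composition_*.tsv and results/kmer_oe_*.tsv")
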