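#' Published genome-wide summary counts for the X. tropicalis GV datasets
#'
#' Raw summary cells of the published genome-wide sisRNA characterization in
#' Xenopus tropicalis germinal vesicles (peak dataset sizes, per-intron-count
#' gene groups for the RefSeq and Ensembl references, and pooled base
#' compositions). Only raw counts are stored; every derived quantity (mean
#' length, percent of genome, group percentages, per-gene and per-intron
#' ratios, GC percentage) is recomputed by the package's summary operations,
#' which makes the published tables a desk-scale consistency check of that
#' arithmetic.
#'
#' @return A list with elements `peak_datasets`, `intron_groups_refseq`,
#'   `intron_groups_ensembl` and `base_composition`, each a data.frame of raw
#'   cells.
#' @export
published_gv_summaries <- function() {
  read_one <- function(name) {
    utils::read.table(system.file("extdata", name, package = "sisprofiler",
                                  mustWork = TRUE),
                      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  list(peak_datasets = read_one("gv_peak_datasets.tsv"),
       intron_groups_refseq = read_one("gv_intron_groups_refseq.tsv"),
       intron_groups_ensembl = read_one("gv_intron_groups_ensembl.tsv"),
       base_composition = read_one("gv_base_composition.tsv"))
}

#' Recompute derived group-summary cells from published raw counts
#'
#' Applies [group_summary()] to every intron-count group row of a published
#' raw-count table (one of the `intron_groups_*` elements of
#' [published_gv_summaries()]) and appends the Total row, with ratios over
#' intron-containing genes only.
#'
#' @param groups Raw-count data.frame with columns `intron_count_group`,
#'   `n_genes`, `n_total_introns`, `n_genes_with_sisrna`, `n_sisrnas` (the
#'   `0` group row carries NA sisRNA cells).
#' @return A data.frame of [group_summary()] rows plus a Total row.
#' @export
published_group_table <- function(groups) {
  zero <- groups$intron_count_group == "0"
  with_introns <- groups[!zero, , drop = FALSE]
  rows <- lapply(seq_len(nrow(with_introns)), function(i)
    group_summary(with_introns$intron_count_group[i],
                  with_introns$n_genes[i],
                  with_introns$n_total_introns[i],
                  with_introns$n_genes_with_sisrna[i],
                  with_introns$n_sisrnas[i]))
  total <- group_summary("Total",
                         n_genes = sum(groups$n_genes),
                         n_total_introns = sum(with_introns$n_total_introns),
                         n_genes_with_sisrna = sum(with_introns$n_genes_with_sisrna),
                         n_sisrnas = sum(with_introns$n_sisrnas),
                         denominator_genes = sum(with_introns$n_genes))
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  out
}
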