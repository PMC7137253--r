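#' Caller configuration
#'
#' @param min_length Minimum accepted peak length in base pairs (inclusive;
#'   default 150, chosen to exclude short non-coding RNA contamination such as
#'   miRNA/siRNA/piRNA).
#' @param multi_gene_policy `"per_gene"` (a peak contained in introns of
#'   several overlapping genes yields one sisRNA per host gene) or
#'   `"unique_only"` (such peaks are dropped).
#' @return A list of class `"caller_config"`.
#' @export
caller_config <- function(min_length = 150L,
                          multi_gene_policy = c("per_gene", "unique_only")) {
  stopifnot(min_length > 0)
  structure(list(min_length = as.integer(min_length),
                 multi_gene_policy = match.arg(multi_gene_policy)),
            class = "caller_config")
}

#' Classify RNA peaks into sisRNAs
#'
#' A peak is accepted as a sisRNA when it lies entirely within an intron, does
#' not overlap any exon of any gene in the reference set, and is at least
#' `min_length` base pairs long. Under the default `per_gene` policy a peak
#' fully contained in introns of more than one (overlapping) gene is reported
#' once per host gene.
#'
#' @param peaks A [GenomicRanges::GRanges] of peaks (see [read_peaks()]).
#' @param genes A gene-model [GenomicRanges::GRangesList].
#' @param config A [caller_config()].
#' @param introns Optional precomputed [derive_introns()] output (recomputed
#'   otherwise).
#' @return A [GenomicRanges::GRanges] of accepted sisRNAs, one row per
#'   (peak, host gene) assignment, with metadata columns `peak_id`, `signal`,
#'   `summit`, `fdr`, `host_gene_id` and `host_intron_ordinal`. Peaks on
#'   scaffolds absent from the gene set are skipped with a warning.
#' @export
classify_peaks <- function(peaks, genes, config = caller_config(),
                           introns = NULL) {
  stopifnot(inherits(config, "caller_config"))
  if (is.null(introns)) introns <- derive_introns(genes)
  exons <- GenomicRanges::reduce(unlist(genes, use.names = FALSE),
                                 ignore.strand = TRUE)
  known <- unique(as.character(GenomicRanges::seqnames(
    unlist(genes, use.names = FALSE))))
  on_known <- as.character(GenomicRanges::seqnames(peaks)) %in% known
  if (!all(on_known)) {
    warning(sum(!on_known), " peak(s) on scaffold(s) unknown to the gene set",
            " were skipped")
    peaks <- peaks[on_known]
  }
  if (is.null(peaks$name)) peaks$name <- sprintf("peak_%05d", seq_along(peaks))

  long_enough <- GenomicRanges::width(peaks) >= config$min_length
  exon_clean <- GenomicRanges::countOverlaps(peaks, exons,
                                             ignore.strand = TRUE) == 0L
  candidate <- peaks[long_enough & exon_clean]
  hits <- GenomicRanges::findOverlaps(candidate, introns, type = "within",
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (config$multi_gene_policy == "unique_only") {
    n_genes_hit <- tapply(introns$gene_id[si], qi, function(g)
      length(unique(g)))
    multi <- as.integer(names(n_genes_hit)[n_genes_hit > 1L])
    keep <- !(qi %in% multi)
    qi <- qi[keep]; si <- si[keep]
  }
  sis <- GenomicRanges::granges(candidate)[qi]
  sis$peak_id <- candidate$name[qi]
  sis$signal <- if (!is.null(candidate$signal)) candidate$signal[qi] else NA_real_
  sis$summit <- if (!is.null(candidate$summit)) candidate$summit[qi] else NA_integer_
  sis$fdr <- if (!is.null(candidate$fdr)) candidate$fdr[qi] else NA_real_
  sis$host_gene_id <- introns$gene_id[si]
  sis$host_intron_ordinal <- introns$ordinal[si]
  sis
}

#' Per-gene sisRNA counts
#'
#' @param sisrnas Output of [classify_peaks()].
#' @param genes The gene-model [GenomicRanges::GRangesList] used for
#'   classification.
#' @return A data.frame with one row per gene: `gene_id`, `n_introns`,
#'   `n_sisrnas` (number of (sisRNA, host gene) assignments; multiple sisRNAs
#'   in one intron all count).
#' @export
count_per_gene <- function(sisrnas, genes) {
  n_introns <- lengths(genes) - 1L
  counts <- table(factor(sisrnas$host_gene_id, levels = names(genes)))
  data.frame(gene_id = names(genes),
             n_introns = as.integer(n_introns),
             n_sisrnas = as.integer(counts[names(genes)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Unique sisRNA intervals
#'
#' Collapses per-gene assignments back to unique peak intervals (a peak hosted
#' by two overlapping genes appears once), for length and genome-fraction
#' summaries.
#'
#' @param sisrnas Output of [classify_peaks()].
#' @return A [GenomicRanges::GRanges] with one row per distinct peak.
#' @export
unique_sisrnas <- function(sisrnas) {
  key <- paste(as.character(GenomicRanges::seqnames(sisrnas)),
               GenomicRanges::start(sisrnas), GenomicRanges::end(sisrnas),
               sisrnas$peak_id)
  sisrnas[!duplicated(key)]
}
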