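#' Dataset-level sisRNA summary from raw counts
#'
#' Derived cells (mean length, percent of genome) are computed from the raw
#' ones, so a printed summary table can be checked for internal consistency.
#'
#' @param n_sisrnas Number of sisRNAs.
#' @param total_length Summed sisRNA length in base pairs.
#' @param genome_length Genome size in base pairs.
#' @param min_length,median_length,max_length Optional order statistics.
#' @return A one-row data.frame: `n_sisrnas`, `total_length`,
#'   `pct_of_genome`, `mean_length`, `min_length`, `median_length`,
#'   `max_length`.
#' @export
dataset_summary <- function(n_sisrnas, total_length, genome_length,
                            min_length = NA_real_, median_length = NA_real_,
                            max_length = NA_real_) {
  stopifnot(n_sisrnas >= 1, total_length > 0, genome_length > 0)
  data.frame(n_sisrnas = n_sisrnas,
             total_length = total_length,
             pct_of_genome = 100 * total_length / genome_length,
             mean_length = total_length / n_sisrnas,
             min_length = min_length,
             median_length = median_length,
             max_length = max_length)
}

#' Summarize a sisRNA dataset
#'
#' Lengths are taken over unique peak intervals (a peak assigned to several
#' overlapping host genes is counted once). The median of an even-count set
#' is the mean of the two central values.
#'
#' @param sisrnas Output of [classify_peaks()].
#' @param genome The genome ([Biostrings::DNAStringSet]).
#' @return A one-row data.frame, see [dataset_summary()].
#' @export
summarize_dataset <- function(sisrnas, genome) {
  u <- unique_sisrnas(sisrnas)
  if (length(u) == 0L) stop("no sisRNAs to summarize")
  w <- GenomicRanges::width(u)
  dataset_summary(n_sisrnas = length(u),
                  total_length = sum(as.numeric(w)),
                  genome_length = genome_length(genome),
                  min_length = min(w),
                  median_length = stats::median(w),
                  max_length = max(w))
}

#' One intron-count group summary row from raw counts
#'
#' Percentage and per-gene ratios divide by `denominator_genes` (by default
#' the printed gene count); a Total row over a gene set that also contains
#' intron-less genes passes the intron-containing gene count as denominator
#' while still printing the full count, since intron-less genes are excluded
#' from ratio denominators.
#'
#' @param intron_count_group Group label (e.g. `"1"`, `">=10"`, `"Total"`).
#' @param n_genes Printed number of genes in the group.
#' @param n_total_introns Summed intron count of the group.
#' @param n_genes_with_sisrna Genes in the group hosting >= 1 sisRNA.
#' @param n_sisrnas Summed (sisRNA, host gene) assignments in the group.
#' @param denominator_genes Denominator for percentage and per-gene ratio.
#' @return A one-row data.frame with the raw cells plus
#'   `pct_genes_with_sisrna`, `sisrnas_per_gene`, `sisrnas_per_intron`.
#' @export
group_summary <- function(intron_count_group, n_genes, n_total_introns,
                          n_genes_with_sisrna, n_sisrnas,
                          denominator_genes = n_genes) {
  data.frame(
    intron_count_group = as.character(intron_count_group),
    n_genes = n_genes,
    n_total_introns = n_total_introns,
    n_genes_with_sisrna = n_genes_with_sisrna,
    pct_genes_with_sisrna = 100 * n_genes_with_sisrna / denominator_genes,
    n_sisrnas = n_sisrnas,
    sisrnas_per_gene = n_sisrnas / denominator_genes,
    sisrnas_per_intron = if (n_total_introns > 0)
      n_sisrnas / n_total_introns else NA_real_,
    stringsAsFactors = FALSE)
}

#' Group genes by intron count and summarize sisRNA incidence
#'
#' Genes are grouped by intron count into groups 1..9 plus a pooled ">=10"
#' group; intron-less genes are excluded from all ratios (and from group
#' rows), but still counted in the Total row's printed gene number. Empty
#' groups are omitted.
#'
#' @param per_gene_counts Output of [count_per_gene()] (may include 0-intron
#'   genes).
#' @return A data.frame of [group_summary()] rows plus a `"Total"` row.
#' @export
group_by_intron_count <- function(per_gene_counts) {
  df <- per_gene_counts
  with_introns <- df[df$n_introns > 0L, ]
  grp <- ifelse(with_introns$n_introns >= 10L, ">=10",
                as.character(with_introns$n_introns))
  levels_ <- c(as.character(1:9), ">=10")
  rows <- lapply(levels_, function(g) {
    d <- with_introns[grp == g, ]
    if (nrow(d) == 0L) return(NULL)
    group_summary(g, nrow(d), sum(d$n_introns), sum(d$n_sisrnas > 0L),
                  sum(d$n_sisrnas))
  })
  total <- group_summary("Total",
                         n_genes = nrow(df),
                         n_total_introns = sum(df$n_introns),
                         n_genes_with_sisrna = sum(with_introns$n_sisrnas > 0L),
                         n_sisrnas = sum(with_introns$n_sisrnas),
                         denominator_genes = nrow(with_introns))
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with validity checks
#'
#' @param x,y Paired numeric observations (>= 3 pairs after NA removal).
#' @return The Pearson product-moment coefficient; `NA` with a warning when
#'   either variable has zero variance.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Correlation between sisRNA peak signal and host-gene expression
#'
#' One point per (sisRNA, host gene) assignment; the peak signal column is
#' used as provided. Assignments whose host gene is missing from the FPKM
#' table are dropped and counted.
#'
#' @param sisrnas Output of [classify_peaks()].
#' @param fpkm A data.frame with columns `gene_id` and `fpkm` (see
#'   [read_fpkm()]).
#' @return A list: `r` (Pearson R over pairs), `n_pairs`, `n_dropped`, and
#'   `data` (the joined signal/FPKM pairs).
#' @export
correlate_signal_expression <- function(sisrnas, fpkm) {
  idx <- match(sisrnas$host_gene_id, fpkm$gene_id)
  dropped <- is.na(idx)
  if (all(dropped)) stop("no sisRNA host gene found in the FPKM table")
  d <- data.frame(gene_id = sisrnas$host_gene_id[!dropped],
                  signal = sisrnas$signal[!dropped],
                  fpkm = fpkm$fpkm[idx[!dropped]],
                  stringsAsFactors = FALSE)
  r <- if (nrow(d) >= 3L) correlate(d$signal, d$fpkm) else {
    warning("fewer than 3 (sisRNA, host gene) pairs: correlation undefined")
    NA_real_
  }
  list(r = r,
       n_pairs = nrow(d),
       n_dropped = sum(dropped),
       data = d)
}

#' Overlap of two host-gene sets against a random-selection expectation
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates removed).
#' @param universe_size Number of genes both sets are drawn from.
#' @return A list: `n_a`, `n_b`, `n_overlap`, `expected_overlap`
#'   (`n_a * n_b / universe_size`, the mean overlap of two random subsets of
#'   these sizes).
#' @export
host_gene_overlap <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  stopifnot(universe_size >= max(length(a), length(b)))
  list(n_a = length(a), n_b = length(b),
       n_overlap = length(intersect(a, b)),
       expected_overlap = length(a) * length(b) / universe_size)
}
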