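#' Concatenate the introns of one gene into a joined transcript
#'
#' Builds the joined intron coordinate axis: all introns of a gene laid end to
#' end in transcription (5' to 3') order, so joined position 1 is the 5'-most
#' intron base. For minus-strand genes each segment runs right-to-left in
#' scaffold coordinates.
#'
#' @param introns [derive_introns()] output restricted to (or filtered for)
#'   one gene.
#' @param gene_id Gene to extract when `introns` holds several genes.
#' @return An object of class `"joined_introns"`: `gene_id`, `strand`,
#'   `segments` (data.frame with scaffold/genomic start/end/ordinal and joined
#'   start/end) and `total_length`.
#' @export
concatenate_introns <- function(introns, gene_id = NULL) {
  if (!is.null(gene_id)) introns <- introns[introns$gene_id == gene_id]
  if (length(introns) == 0L) stop("gene has no introns")
  gid <- unique(introns$gene_id)
  stopifnot(length(gid) == 1L)
  ord <- order(introns$ordinal)
  introns <- introns[ord]
  w <- GenomicRanges::width(introns)
  joined_end <- cumsum(w)
  seg <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(introns)),
    start = GenomicRanges::start(introns),
    end = GenomicRanges::end(introns),
    ordinal = introns$ordinal,
    joined_start = joined_end - w + 1L,
    joined_end = joined_end,
    stringsAsFactors = FALSE)
  structure(list(gene_id = gid,
                 strand = as.character(GenomicRanges::strand(introns))[1L],
                 segments = seg,
                 total_length = sum(w)),
            class = "joined_introns")
}

#' @export
print.joined_introns <- function(x, ...) {
  cat("joined_introns [", x$gene_id, "]: ", nrow(x$segments),
      " intron(s), ", x$total_length, " bp, strand ", x$strand, "\n", sep = "")
  invisible(x)
}

#' Map joined positions to genomic positions
#'
#' @param joined A `"joined_introns"` object.
#' @param pos Joined positions (1-based, in `[1, total_length]`).
#' @return Genomic positions (1-based scaffold coordinates).
#' @export
joined_to_genomic <- function(joined, pos) {
  stopifnot(all(pos >= 1L), all(pos <= joined$total_length))
  seg <- joined$segments
  i <- findInterval(pos, seg$joined_start)
  off <- pos - seg$joined_start[i]
  if (joined$strand == "-") seg$end[i] - off else seg$start[i] + off
}

#' Map genomic positions to joined positions
#'
#' @param joined A `"joined_introns"` object.
#' @param pos Genomic positions; every position must fall inside an intron of
#'   the gene.
#' @return Joined positions.
#' @export
genomic_to_joined <- function(joined, pos) {
  seg <- joined$segments
  i <- vapply(pos, function(p) {
    j <- which(p >= seg$start & p <= seg$end)
    if (length(j) != 1L) stop("position ", p, " is not intronic for ",
                              joined$gene_id)
    j
  }, integer(1))
  if (joined$strand == "-") seg$joined_start[i] + (seg$end[i] - pos)
  else seg$joined_start[i] + (pos - seg$start[i])
}

#' Per-gene binned sisRNA density along the joined intron transcript
#'
#' The joined transcript of length L is split into `n_bins` bins by integer
#' partition (bin b covers joined positions floor((b-1)*L/n)+1 ..
#' floor(b*L/n); bin lengths differ by at most 1). Den_b is the fraction of
#' positions in bin b covered by at least one sisRNA of the gene.
#'
#' @param joined A `"joined_introns"` object.
#' @param sisrnas [classify_peaks()] output (assignments for other genes are
#'   ignored).
#' @param n_bins Number of bins (default 100).
#' @return An object of class `"density_profile"`: `gene_id`, `bins` (numeric
#'   `n_bins` vector of Den_b), `bin_lengths`, `n_genes = 1`.
#' @export
bin_density <- function(joined, sisrnas, n_bins = 100L) {
  L <- joined$total_length
  if (L < n_bins)
    stop("joined intron transcript shorter than n_bins (", L, " < ", n_bins,
         "): density bins undefined")
  seg <- joined$segments
  s <- sisrnas[sisrnas$host_gene_id == joined$gene_id]
  covered <- IRanges::IRanges()
  if (length(s) > 0L) {
    i <- match(s$host_intron_ordinal, seg$ordinal)
    if (anyNA(i)) stop("sisRNA assigned to unknown intron ordinal")
    gs <- GenomicRanges::start(s); ge <- GenomicRanges::end(s)
    if (any(gs < seg$start[i]) || any(ge > seg$end[i]))
      stop("sisRNA not contained in its host intron")
    if (joined$strand == "-") {
      js <- seg$joined_start[i] + (seg$end[i] - ge)
      je <- seg$joined_start[i] + (seg$end[i] - gs)
    } else {
      js <- seg$joined_start[i] + (gs - seg$start[i])
      je <- seg$joined_start[i] + (ge - seg$start[i])
    }
    covered <- IRanges::reduce(IRanges::IRanges(js, je))
  }
  b <- seq_len(n_bins)
  lo <- floor((b - 1) * L / n_bins) + 1
  hi <- floor(b * L / n_bins)
  bins_ir <- IRanges::IRanges(lo, hi)
  cov_vec <- IRanges::coverage(covered, width = L) > 0L
  csum <- cumsum(as.integer(cov_vec))
  covered_in_bin <- csum[hi] - c(0, csum[lo[-1L] - 1L])
  den <- covered_in_bin / (hi - lo + 1)
  structure(list(gene_id = joined$gene_id,
                 bins = as.numeric(den),
                 bin_lengths = as.integer(hi - lo + 1),
                 n_genes = 1L),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile [", x$gene_id, "]: ", length(x$bins), " bins, ",
      x$n_genes, " gene(s), mean density ",
      sprintf("%.4f", mean(x$bins)), "\n", sep = "")
  invisible(x)
}

#' Aggregate per-gene density profiles
#'
#' Unweighted mean per bin across genes: each gene contributes equally
#' regardless of its joined transcript length.
#'
#' @param profiles A list of `"density_profile"` objects with equal bin
#'   counts.
#' @return A `"density_profile"` with `gene_id = "aggregate"` and `n_genes`
#'   the number of profiles.
#' @export
aggregate_density <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  nb <- unique(vapply(profiles, function(p) length(p$bins), integer(1)))
  stopifnot(length(nb) == 1L)
  m <- vapply(profiles, function(p) p$bins, numeric(nb))
  bins <- if (is.matrix(m)) rowMeans(m) else m
  structure(list(gene_id = "aggregate",
                 bins = as.numeric(bins),
                 bin_lengths = NULL,
                 n_genes = length(profiles)),
            class = "density_profile")
}

#' Binned sisRNA density over a whole gene set
#'
#' Convenience wrapper: joins introns, bins per-gene densities and aggregates
#' them. Genes whose joined intron transcript is shorter than `n_bins` are
#' excluded (their bins would be empty) and their number reported.
#'
#' @param introns [derive_introns()] output for the gene set.
#' @param sisrnas [classify_peaks()] output.
#' @param n_bins Number of bins (default 100).
#' @return A list: `aggregate` (`"density_profile"`), `per_gene` (named list
#'   of per-gene profiles) and `n_excluded_short`.
#' @export
intron_density_profiles <- function(introns, sisrnas, n_bins = 100L) {
  gene_ids <- unique(introns$gene_id)
  per_gene <- list()
  n_excluded <- 0L
  for (g in gene_ids) {
    joined <- concatenate_introns(introns, g)
    if (joined$total_length < n_bins) {
      n_excluded <- n_excluded + 1L
      next
    }
    per_gene[[g]] <- bin_density(joined, sisrnas, n_bins = n_bins)
  }
  if (length(per_gene) == 0L) stop("no gene with joined intron length >= n_bins")
  if (n_excluded > 0L)
    message(n_excluded, " gene(s) with joined intron length < ", n_bins,
            " excluded from density aggregation")
  list(aggregate = aggregate_density(per_gene),
       per_gene = per_gene,
       n_excluded_short = n_excluded)
}
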