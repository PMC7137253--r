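#' Extract region sequences from a genome
#'
#' @param regions A [GenomicRanges::GRanges].
#' @param genome A [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet], one sequence per region, + strand of
#'   the scaffold (all composition metrics reported by this package are
#'   reverse-complement symmetric under class collapsing, so the strand of
#'   extraction does not matter).
#' @export
region_seqs <- function(regions, genome) {
  sn <- as.character(GenomicRanges::seqnames(regions))
  if (!all(sn %in% names(genome)))
    stop("region(s) on scaffold absent from genome: ",
         paste(unique(setdiff(sn, names(genome))), collapse = ", "))
  sl <- seqlengths_from_genome(genome)
  if (any(GenomicRanges::start(regions) < 1L) ||
      any(GenomicRanges::end(regions) > sl[sn]))
    stop("region(s) outside scaffold bounds")
  out <- Biostrings::DNAStringSet(rep("", length(regions)))
  for (sc in unique(sn)) {
    i <- which(sn == sc)
    out[i] <- Biostrings::extractAt(
      genome[[sc]], IRanges::IRanges(GenomicRanges::start(regions)[i],
                                     GenomicRanges::end(regions)[i]))
  }
  names(out) <- if (!is.null(names(regions))) names(regions) else NULL
  out
}

#' The whole genome as a region set
#'
#' One region per scaffold, spanning it entirely — the background region set
#' for composition and enrichment identities.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A [GenomicRanges::GRanges].
#' @export
whole_genome_regions <- function(genome) {
  GenomicRanges::GRanges(names(genome),
                         IRanges::IRanges(1L, Biostrings::width(genome)))
}

#' Pooled base composition of a region set
#'
#' Counts are pooled over all regions; N bases are excluded from the
#' denominator (fractions are over non-N bases only).
#'
#' @param regions A [GenomicRanges::GRanges] (or a [Biostrings::DNAStringSet]
#'   of already-extracted sequences).
#' @param genome A [Biostrings::DNAStringSet]; ignored when `regions` is
#'   already a sequence set.
#' @param region_set_id Label carried into the result.
#' @return A list of class `"composition_profile"` with `region_set_id`,
#'   `total_bases` (non-N), `base_fractions` (named A/C/G/T, summing to 1) and
#'   `gc_fraction`.
#' @export
base_composition <- function(regions, genome = NULL, region_set_id = "regions") {
  seqs <- if (inherits(regions, "DNAStringSet")) regions else
    region_seqs(regions, genome)
  if (length(seqs) == 0L) stop("empty region set")
  af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  counts <- af[c("A", "C", "G", "T")]
  total <- sum(counts)
  if (total == 0L) stop("region set contains no non-N bases")
  fr <- counts / total
  structure(list(region_set_id = region_set_id,
                 total_bases = total,
                 base_fractions = fr,
                 gc_fraction = unname(fr[["C"]] + fr[["G"]])),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("composition_profile [", x$region_set_id, "]: ",
      format(x$total_bases, big.mark = ","), " non-N bases, GC ",
      sprintf("%.2f%%", 100 * x$gc_fraction), "\n", sep = "")
  invisible(x)
}

#' Dinucleotide density of a region set
#'
#' Occurrences are counted at every offset within each region independently
#' (overlapping occurrences count; dinucleotides spanning region boundaries do
#' not). Windows containing N are skipped. Density is reported per 100 bases
#' of (non-N) region sequence.
#'
#' @param regions A [GenomicRanges::GRanges] or [Biostrings::DNAStringSet].
#' @param genome Genome (ignored for a sequence set).
#' @param class `"CG"` (CpG) or `"CA|TG"` (the CA/TG reverse-complement pair).
#' @return Density per 100 bases (a single number).
#' @export
dinucleotide_density <- function(regions, genome = NULL,
                                 class = c("CG", "CA|TG")) {
  class <- match.arg(class)
  seqs <- if (inherits(regions, "DNAStringSet")) regions else
    region_seqs(regions, genome)
  if (length(seqs) == 0L) stop("empty region set")
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 2L,
                                                 simplify.as = "collapsed")
  n <- if (class == "CG") counts[["CG"]] else counts[["CA"]] + counts[["TG"]]
  total <- sum(Biostrings::alphabetFrequency(seqs,
                                             collapse = TRUE)[c("A", "C", "G", "T")])
  100 * n / total
}

#' Reverse-complement-collapsed k-mer classes
#'
#' Each k-mer is pooled with its reverse complement; the representative is the
#' lexicographically smaller member. k = 2 yields 10 classes, k = 3 yields 32.
#'
#' @param k Word size (2 or 3).
#' @return A data.frame with columns `representative` and `members`
#'   (slash-separated).
#' @export
kmer_classes <- function(k) {
  stopifnot(k %in% c(2L, 3L))
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  rep_ <- pmin(kmers, rc)
  cls <- unique(rep_)
  members <- vapply(cls, function(r)
    paste(sort(unique(c(r, rc[match(r, kmers)]))), collapse = "/"),
    character(1))
  data.frame(representative = cls, members = unname(members),
             stringsAsFactors = FALSE)
}

kmer_class_freq <- function(seqs, k) {
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k,
                                                 simplify.as = "collapsed")
  total <- sum(counts)
  kmers <- names(counts)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  rep_ <- pmin(kmers, rc)
  cls_counts <- tapply(counts, rep_, sum)
  list(freq = cls_counts / total, total_offsets = total)
}

#' k-mer observed/expected ratios for a region set
#'
#' Observed frequencies are pooled k-mer class frequencies over the region
#' set; expected frequencies come from the background model. With the default
#' genome background, O/E is the relative prevalence of each collapsed k-mer
#' class in the regions versus the whole genome (the whole genome as its own
#' region set gives O/E = 1 for every class). The alternative
#' `"mononucleotide"` background uses the product of region base frequencies
#' (the CpG-island-style expectation). Any k-mer containing N is skipped in
#' both numerator and offset denominator.
#'
#' @param regions A [GenomicRanges::GRanges] or [Biostrings::DNAStringSet].
#' @param genome A [Biostrings::DNAStringSet] (also supplies the background
#'   for `background = "genome"`).
#' @param k Word size (2 or 3).
#' @param background `"genome"` or `"mononucleotide"`.
#' @return A data.frame with one row per collapsed class: `representative`,
#'   `members`, `observed` (class frequency in regions), `expected` and `oe`.
#'   Classes with zero expected frequency get `oe = NA` and are flagged in the
#'   `undefined` column. The background used is recorded in
#'   `attr(, "background")`.
#' @export
kmer_oe <- function(regions, genome, k,
                    background = c("genome", "mononucleotide")) {
  background <- match.arg(background)
  stopifnot(k %in% c(2L, 3L))
  seqs <- if (inherits(regions, "DNAStringSet")) regions else
    region_seqs(regions, genome)
  obs <- kmer_class_freq(seqs, k)
  cls <- kmer_classes(k)
  if (background == "genome") {
    bg <- kmer_class_freq(genome, k)
    expected <- as.numeric(bg$freq[cls$representative])
  } else {
    fr <- base_composition(seqs)$base_fractions
    kmer_prob <- function(word) prod(fr[strsplit(word, "")[[1L]]])
    expected <- vapply(strsplit(cls$members, "/"), function(m)
      sum(vapply(m, kmer_prob, numeric(1))), numeric(1))
  }
  observed <- as.numeric(obs$freq[cls$representative])
  observed[is.na(observed)] <- 0
  oe <- ifelse(expected > 0, observed / expected, NA_real_)
  out <- data.frame(cls, observed = observed, expected = expected, oe = oe,
                    undefined = expected == 0, stringsAsFactors = FALSE)
  attr(out, "background") <- background
  out
}

#' Full composition profile of a region set
#'
#' @inheritParams kmer_oe
#' @param region_set_id Label carried into the result.
#' @param k Word sizes for O/E maps (default both 2 and 3).
#' @return A `"composition_profile"` (see [base_composition()]) extended with
#'   `cpg_density`, `catg_density` (both per 100 bases) and `kmer_oe`, a list
#'   of [kmer_oe()] tables keyed `"k2"`, `"k3"`.
#' @export
composition_profile <- function(regions, genome, region_set_id = "regions",
                                k = c(2L, 3L),
                                background = c("genome", "mononucleotide")) {
  background <- match.arg(background)
  seqs <- if (inherits(regions, "DNAStringSet")) regions else
    region_seqs(regions, genome)
  prof <- base_composition(seqs, region_set_id = region_set_id)
  prof$cpg_density <- dinucleotide_density(seqs, class = "CG")
  prof$catg_density <- dinucleotide_density(seqs, class = "CA|TG")
  prof$kmer_oe <- lapply(stats::setNames(as.integer(k), paste0("k", k)),
                         function(kk) kmer_oe(seqs, genome, kk,
                                              background = background))
  prof
}

#' Per-region composition values
#'
#' Computes GC fraction, CpG density and CA|TG density separately for every
#' region (the per-region distributions behind boxplot-style comparisons, as
#' opposed to the pooled values of [composition_profile()]).
#'
#' @inheritParams base_composition
#' @return A data.frame with one row per region: `region`, `n_bases` (non-N),
#'   `gc_fraction`, `cpg_density`, `catg_density`. Regions with no non-N base
#'   get `NA` metrics.
#' @export
per_region_composition <- function(regions, genome = NULL) {
  seqs <- if (inherits(regions, "DNAStringSet")) regions else
    region_seqs(regions, genome)
  af <- Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"), drop = FALSE]
  n <- rowSums(af)
  di <- Biostrings::oligonucleotideFrequency(seqs, width = 2L)
  data.frame(
    region = if (!is.null(names(seqs))) names(seqs) else seq_along(seqs),
    n_bases = n,
    gc_fraction = ifelse(n > 0, (af[, "C"] + af[, "G"]) / n, NA_real_),
    cpg_density = ifelse(n > 0, 100 * di[, "CG"] / n, NA_real_),
    catg_density = ifelse(n > 0, 100 * (di[, "CA"] + di[, "TG"]) / n, NA_real_),
    stringsAsFactors = FALSE)
}

#' Long-format comparison of per-region composition across sets
#'
#' @param sets Named list of [per_region_composition()] tables (>= 2).
#' @return A list with `values` (long data.frame: `set`, `region`, `metric`,
#'   `value`) and `summary` (per set and metric: median and quartiles).
#' @export
compare_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  metrics <- c("gc_fraction", "cpg_density", "catg_density")
  long <- do.call(rbind, lapply(names(sets), function(nm) {
    df <- sets[[nm]]
    do.call(rbind, lapply(metrics, function(m)
      data.frame(set = nm, region = df$region, metric = m, value = df[[m]],
                 stringsAsFactors = FALSE)))
  }))
  long <- long[!is.na(long$value), ]
  summ <- do.call(rbind, lapply(split(long, long[c("set", "metric")]),
                                function(d) data.frame(
    set = d$set[1L], metric = d$metric[1L], n = nrow(d),
    q1 = stats::quantile(d$value, 0.25, names = FALSE),
    median = stats::median(d$value),
    q3 = stats::quantile(d$value, 0.75, names = FALSE),
    stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(values = long, summary = summ)
}
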