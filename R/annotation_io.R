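#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a [Biostrings::DNAStringSet], keyed by the
#' first whitespace-delimited token of each header. Sequence is uppercased and
#' restricted to the A/C/G/T/N alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by scaffold.
#' @export
load_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0L)
    stop("FASTA file contains no records: ", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate scaffold name(s) in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  if (any(Biostrings::width(genome) == 0L))
    stop("empty scaffold record(s) in FASTA")
  genome <- Biostrings::DNAStringSet(toupper(genome))
  af <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  bad <- af[!names(af) %in% c("A", "C", "G", "T", "N")]
  if (sum(bad) > 0L)
    stop("genome contains letters outside {A,C,G,T,N}: ",
         paste(names(bad)[bad > 0], collapse = ", "))
  genome
}

#' Total genome length in base pairs
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Total number of base pairs over all scaffolds (includes N bases).
#' @export
genome_length <- function(genome) {
  sum(as.numeric(Biostrings::width(genome)))
}

seqlengths_from_genome <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Load gene models
#'
#' Reads gene models from a genePred or GTF file into one merged exon set per
#' gene: exons of all isoforms sharing a `gene_id` are unioned (overlapping
#' exon intervals merged), so each gene has a single, disjoint, sorted exon
#' chain and a single intron set. Internal coordinates are 1-based closed
#' ([GenomicRanges::GRanges] convention); genePred's 0-based half-open starts
#' are shifted on read.
#'
#' @param path Path to the annotation file.
#' @param dialect `"genepred"` or `"gtf"`.
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, exons
#'   falling outside scaffold bounds (or on unknown scaffolds) are an error.
#' @return A [GenomicRanges::GRangesList] of merged exons, one element per
#'   gene, named by `gene_id`, with strand set on every exon.
#' @export
load_gene_models <- function(path, dialect = c("genepred", "gtf"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "genepred") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#",
                             quote = "")
    if (ncol(tab) < 10L)
      stop("genePred file must have >= 10 tab-separated columns")
    exon_starts <- strsplit(sub(",$", "", tab[[9L]]), ",", fixed = TRUE)
    exon_ends <- strsplit(sub(",$", "", tab[[10L]]), ",", fixed = TRUE)
    n_ex <- tab[[8L]]
    if (!all(lengths(exon_starts) == n_ex) || !all(lengths(exon_ends) == n_ex))
      stop("genePred exonCount does not match exonStarts/exonEnds")
    if (!all(tab[[3L]] %in% c("+", "-")))
      stop("unknown strand symbol in genePred: ",
           paste(setdiff(unique(tab[[3L]]), c("+", "-")), collapse = ", "))
    exons <- GenomicRanges::GRanges(
      seqnames = rep(tab[[2L]], n_ex),
      ranges = IRanges::IRanges(
        start = as.integer(unlist(exon_starts)) + 1L,  # 0-based -> 1-based
        end = as.integer(unlist(exon_ends))),
      strand = rep(tab[[3L]], n_ex),
      gene_id = rep(tab[[1L]], n_ex))
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("GTF contains no exon records")
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("GTF exon records lack gene_id attributes")
    if (any(GenomicRanges::strand(gr) == "*"))
      stop("unknown strand symbol in GTF exon record")
    exons <- GenomicRanges::granges(gr)
    exons$gene_id <- gr$gene_id
  }
  gene_models_from_exons(exons, genome = genome)
}

#' Assemble gene models from a flat exon set
#'
#' @param exons A [GenomicRanges::GRanges] of exons carrying a `gene_id`
#'   metadata column (possibly multiple isoforms per gene).
#' @param genome Optional genome for bounds validation.
#' @return A [GenomicRanges::GRangesList] of merged exons per gene.
#' @export
gene_models_from_exons <- function(exons, genome = NULL) {
  if (!is.null(genome)) {
    sl <- seqlengths_from_genome(genome)
    sn <- as.character(GenomicRanges::seqnames(exons))
    if (!all(sn %in% names(sl)))
      stop("exon(s) on scaffold absent from genome: ",
           paste(unique(setdiff(sn, names(sl))), collapse = ", "))
    if (any(GenomicRanges::start(exons) < 1L) ||
        any(GenomicRanges::end(exons) > sl[sn]))
      stop("exon(s) outside scaffold bounds")
  }
  grl <- GenomicRanges::reduce(S4Vectors::split(
    GenomicRanges::granges(exons), exons$gene_id))
  one_scaffold <- vapply(S4Vectors::runValue(GenomicRanges::seqnames(grl)),
                         length, integer(1)) == 1L
  one_strand <- vapply(S4Vectors::runValue(GenomicRanges::strand(grl)),
                       length, integer(1)) == 1L
  if (!all(one_scaffold & one_strand))
    stop("gene(s) with exons on multiple scaffolds or strands: ",
         paste(names(grl)[!(one_scaffold & one_strand)], collapse = ", "))
  grl
}

#' Per-gene strand
#' @param genes A gene-model [GenomicRanges::GRangesList].
#' @return Named character vector of "+"/"-".
#' @export
gene_strand <- function(genes) {
  vapply(S4Vectors::runValue(GenomicRanges::strand(genes)),
         function(s) as.character(s)[1L], character(1))
}

#' Derive introns from merged gene models
#'
#' Introns are exactly the gaps between consecutive merged exons. Ordinals are
#' 1-based in transcription order: intron 1 is the 5'-most intron, which for a
#' minus-strand gene is the rightmost gap in scaffold coordinates.
#'
#' @param genes A gene-model [GenomicRanges::GRangesList].
#' @return A [GenomicRanges::GRanges] of introns with metadata columns
#'   `gene_id`, `ordinal` and `position_class` (initially `"unclassified"`).
#'   Single-exon genes contribute no introns.
#' @export
derive_introns <- function(genes) {
  span <- unlist(range(genes), use.names = FALSE)
  gaps <- GenomicRanges::psetdiff(span, genes)   # per gene, sorted left-to-right
  n <- lengths(gaps)
  introns <- unlist(gaps, use.names = FALSE)
  gene_id <- rep(names(genes), n)
  minus <- rep(gene_strand(genes) == "-", n)
  # left-to-right index within each gene
  idx <- unlist(lapply(n, seq_len), use.names = FALSE)
  ordinal <- ifelse(minus, rep(n, n) - idx + 1L, idx)
  introns$gene_id <- gene_id
  introns$ordinal <- as.integer(ordinal)
  introns$position_class <- rep("unclassified", length(introns))
  introns
}

#' Classify introns into first (S), middle (M) and last (E) categories
#'
#' Introns of genes with more than 3 introns are labelled S (5'-most, ordinal
#' 1), E (3'-most, ordinal n) or M (all others). Genes with 3 or fewer introns
#' keep `position_class = "unclassified"`.
#'
#' @param introns Output of [derive_introns()].
#' @return The same [GenomicRanges::GRanges] with `position_class` filled in.
#' @export
classify_intron_position <- function(introns) {
  if (length(introns) == 0L) return(introns)
  n_by_gene <- tapply(introns$ordinal, introns$gene_id, max)
  n <- as.integer(n_by_gene[introns$gene_id])
  cls <- rep("unclassified", length(introns))
  eligible <- n > 3L
  cls[eligible & introns$ordinal == 1L] <- "S"
  cls[eligible & introns$ordinal == n] <- "E"
  cls[eligible & introns$ordinal > 1L & introns$ordinal < n] <- "M"
  introns$position_class <- cls
  introns
}

#' Read RNA peaks
#'
#' Reads a BED6-like tab-delimited peak file, optionally extended with MACS
#' style summit and FDR columns (columns 7 and 8: summit offset within the
#' peak, 1-based; FDR as a fraction). BED start coordinates are 0-based
#' half-open and shifted on read.
#'
#' @param path Path to the peak file.
#' @return A [GenomicRanges::GRanges] with metadata columns `name`, `signal`,
#'   `summit` (1-based offset within the peak) and `fdr`.
#' @export
read_peaks <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("peak file must have >= 3 columns")
  start0 <- as.integer(tab[[2L]])
  end <- as.integer(tab[[3L]])
  if (any(end - start0 <= 0L)) stop("peak(s) with non-positive length")
  nm <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
    sprintf("peak_%05d", seq_len(nrow(tab)))
  signal <- if (ncol(tab) >= 5L) as.numeric(tab[[5L]]) else 0
  if (any(signal < 0)) stop("negative peak signal")
  width <- end - start0
  summit <- if (ncol(tab) >= 7L) as.integer(tab[[7L]]) else (width + 1L) %/% 2L
  fdr <- if (ncol(tab) >= 8L) as.numeric(tab[[8L]]) else 0
  if (any(summit < 1L | summit > width)) stop("peak summit outside interval")
  peaks <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    name = nm, signal = signal, summit = summit, fdr = fdr)
  peaks
}

#' Write peaks to a BED6+2 file
#'
#' @param peaks A [GenomicRanges::GRanges] as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$name,
    score = peaks$signal,
    strand = ".",
    summit = peaks$summit,
    fdr = peaks$fdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models to a genePred file
#'
#' One genePred line per gene (the merged exon chain plays the transcript
#' role; cdsStart/cdsEnd are set to the transcript span).
#'
#' @param genes A gene-model [GenomicRanges::GRangesList].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(genes, path) {
  span <- unlist(range(genes), use.names = FALSE)
  starts <- vapply(seq_along(genes), function(i)
    paste0(paste(GenomicRanges::start(genes[[i]]) - 1L, collapse = ","), ","),
    character(1))
  ends <- vapply(seq_along(genes), function(i)
    paste0(paste(GenomicRanges::end(genes[[i]]), collapse = ","), ","),
    character(1))
  df <- data.frame(
    name = names(genes),
    chrom = as.character(GenomicRanges::seqnames(span)),
    strand = gene_strand(genes),
    txStart = GenomicRanges::start(span) - 1L,
    txEnd = GenomicRanges::end(span),
    cdsStart = GenomicRanges::start(span) - 1L,
    cdsEnd = GenomicRanges::end(span),
    exonCount = lengths(genes),
    exonStarts = starts,
    exonEnds = ends)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a conservation track from per-scaffold score vectors
#'
#' @param scores Named list of numeric vectors, one per scaffold, with `NA`
#'   marking positions without a score. Values must lie in `[0, 1]`; values
#'   outside are clamped with a warning.
#' @return An object of class `"conservation_track"`.
#' @export
conservation_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  out_of_range <- vapply(scores, function(v)
    sum(v < 0 | v > 1, na.rm = TRUE), numeric(1))
  if (sum(out_of_range) > 0) {
    warning(sum(out_of_range),
            " conservation score(s) outside [0,1] were clamped")
    scores <- lapply(scores, function(v) pmin(pmax(v, 0), 1))
  }
  structure(list(scores = scores), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  covered <- vapply(x$scores, function(v) sum(!is.na(v)), numeric(1))
  cat("conservation_track:", length(x$scores), "scaffold(s),",
      format(sum(covered), big.mark = ","), "covered base(s)\n")
  invisible(x)
}

#' Load a per-base conservation track
#'
#' Reads wiggle fixedStep/variableStep or bedGraph into per-scaffold score
#' vectors. Positions not covered by any record are `NA`. Wiggle coordinates
#' (1-based) and bedGraph coordinates (0-based half-open) are both mapped onto
#' the internal 1-based axis.
#'
#' @param path Path to the track file.
#' @param genome Optional genome; fixes per-scaffold vector lengths (otherwise
#'   each vector ends at the last covered base of that scaffold).
#' @return A `"conservation_track"` object.
#' @export
load_conservation <- function(path, genome = NULL) {
  head_lines <- readLines(path, n = 50L)
  is_wig <- any(grepl("^(fixedStep|variableStep|track type=wiggle)", head_lines))
  gr <- rtracklayer::import(path, format = if (is_wig) "wig" else "bedGraph")
  sl <- if (!is.null(genome)) seqlengths_from_genome(genome) else
    tapply(GenomicRanges::end(gr), as.character(GenomicRanges::seqnames(gr)), max)
  scores <- lapply(names(sl), function(sc) {
    v <- rep(NA_real_, sl[[sc]])
    g <- gr[GenomicRanges::seqnames(gr) == sc]
    if (length(g) > 0L) {
      w <- GenomicRanges::width(g)
      pos <- sequence(w, from = GenomicRanges::start(g))
      if (any(pos > length(v)))
        stop("conservation record beyond scaffold end on ", sc)
      v[pos] <- rep(g$score, w)
    }
    v
  })
  names(scores) <- names(sl)
  conservation_track(scores)
}

#' Write a conservation track as fixedStep wiggle
#'
#' `NA` runs are omitted (they become uncovered positions on re-read).
#'
#' @param track A `"conservation_track"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sc in names(track$scores)) {
    v <- track$scores[[sc]]
    r <- rle(!is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", sc, starts[i]),
                 con)
      writeLines(format(v[starts[i]:ends[i]], trim = TRUE, scientific = FALSE),
                 con)
    }
  }
  invisible(path)
}

#' Read a gene-expression table
#'
#' Two-column tab-delimited table: gene id, FPKM.
#'
#' @param path Path to the table (a header line `gene_id<tab>fpkm` is
#'   tolerated).
#' @return A data.frame with columns `gene_id` and `fpkm`.
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (identical(tolower(tab[1L, 1L]), "gene_id")) tab <- tab[-1L, , drop = FALSE]
  data.frame(gene_id = as.character(tab[[1L]]), fpkm = as.numeric(tab[[2L]]),
             stringsAsFactors = FALSE)
}
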