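# Small in-code fixtures and independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

make_genome <- function(...) {
  seqs <- c(...)
  DNAStringSet(setNames(as.character(seqs), names(seqs)))
}

random_genome <- function(lengths, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  DNAStringSet(setNames(seqs, names(lengths)))
}

# genes: named list of list(scaffold=, strand=, exons = 2-col matrix of
# (start, end), 1-based closed)
make_genes <- function(genes) {
  rows <- do.call(rbind, lapply(names(genes), function(g) {
    ex <- genes[[g]]$exons
    data.frame(scaffold = genes[[g]]$scaffold,
               start = ex[, 1], end = ex[, 2],
               strand = genes[[g]]$strand, gene_id = g,
               stringsAsFactors = FALSE)
  }))
  gene_models_from_exons(GRanges(rows$scaffold,
                                 IRanges(rows$start, rows$end),
                                 strand = rows$strand,
                                 gene_id = rows$gene_id))
}

make_peaks <- function(scaffold, start, end, signal = NULL, name = NULL) {
  n <- length(start)
  GRanges(scaffold, IRanges(start, end),
          name = if (is.null(name)) sprintf("p%03d", seq_len(n)) else name,
          signal = if (is.null(signal)) rep(1, n) else signal,
          summit = pmax(1L, (end - start + 1L) %/% 2L),
          fdr = rep(0.005, n))
}

# Random multi-gene instance on one scaffold, genes may overlap.
random_instance <- function(seed, n_genes = 10, n_peaks = 300,
                            scaffold_len = 20000) {
  set.seed(seed)
  genes <- list()
  for (i in seq_len(n_genes)) {
    n_ex <- sample(2:6, 1)
    lens <- sample(50:200, n_ex, replace = TRUE)
    gaps <- sample(100:400, n_ex - 1, replace = TRUE)
    span <- sum(lens) + sum(gaps)
    start <- sample.int(scaffold_len - span - 1, 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    cur <- start
    for (k in seq_len(n_ex)) {
      starts[k] <- cur
      ends[k] <- cur + lens[k] - 1L
      if (k < n_ex) cur <- ends[k] + gaps[k] + 1L
    }
    genes[[sprintf("g%02d", i)]] <- list(
      scaffold = "s1", strand = sample(c("+", "-"), 1),
      exons = cbind(starts, ends))
  }
  ps <- sample.int(scaffold_len - 700, n_peaks, replace = TRUE)
  pl <- sample(50:600, n_peaks, replace = TRUE)
  list(genes = make_genes(genes),
       peaks = make_peaks("s1", ps, pmin(ps + pl - 1L, scaffold_len)))
}

# Brute-force per-base sisRNA classification oracle: a (peak, gene, intron)
# triple is accepted iff every peak base lies in that intron, no peak base
# lies in any exon of any gene, and the peak is long enough.
oracle_classify <- function(peaks, genes, min_length = 150) {
  introns <- derive_introns(genes)
  scaffold_len <- max(c(end(unlist(genes)), end(peaks))) + 10L
  exonic <- logical(scaffold_len)
  ex <- unlist(genes, use.names = FALSE)
  for (i in seq_along(ex)) exonic[start(ex)[i]:end(ex)[i]] <- TRUE
  out <- list()
  for (p in seq_along(peaks)) {
    bases <- start(peaks)[p]:end(peaks)[p]
    if (length(bases) < min_length) next
    if (any(exonic[bases])) next
    for (j in seq_along(introns)) {
      if (as.character(seqnames(introns))[j] !=
          as.character(seqnames(peaks))[p]) next
      if (all(bases >= start(introns)[j] & bases <= end(introns)[j])) {
        out[[length(out) + 1L]] <- data.frame(
          peak = p, gene_id = introns$gene_id[j],
          ordinal = introns$ordinal[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peak = integer(0), gene_id = character(0),
                      ordinal = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$peak, df$gene_id, df$ordinal), ]
}

classification_as_df <- function(sisrnas, peaks) {
  key <- paste(as.character(seqnames(sisrnas)), start(sisrnas), end(sisrnas))
  pkey <- paste(as.character(seqnames(peaks)), start(peaks), end(peaks))
  df <- data.frame(peak = match(key, pkey),
                   gene_id = sisrnas$host_gene_id,
                   ordinal = sisrnas$host_intron_ordinal,
                   stringsAsFactors = FALSE)
  df[order(df$peak, df$gene_id, df$ordinal), ]
}

# Naive sliding-window k-mer counter (independent of Biostrings).
oracle_kmer_count <- function(seq_char, word) {
  k <- nchar(word)
  n <- nchar(seq_char)
  if (n < k) return(0L)
  count <- 0L
  for (i in 1:(n - k + 1))
    if (substr(seq_char, i, i + k - 1) == word) count <- count + 1L
  count
}

# Naive per-window PWM log-odds scores (independent loop implementation).
oracle_scan_scores <- function(seq_char, probs, bg) {
  L <- ncol(probs)
  n <- nchar(seq_char)
  if (n < L) return(numeric(0))
  chars <- strsplit(seq_char, "")[[1]]
  vapply(1:(n - L + 1), function(i) {
    w <- chars[i:(i + L - 1)]
    if (any(!w %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(1:L, function(j) log2(probs[w[j], j] / bg[[w[j]]]),
               numeric(1)))
  }, numeric(1))
}

small_bundle_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, scaffold_length = 200000L,
             n_genes = 20L, ...)
}

# Medium scale: enough genes for positional/coupling signs to be stable.
medium_bundle_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_scaffolds = 3L, scaffold_length = 400000L,
             n_genes = 90L, ...)
}

# One default-scale bundle (the generator's study conditions), simulated
# once and shared across test files.
.bundle_cache <- new.env(parent = emptyenv())
get_default_bundle <- function() {
  if (is.null(.bundle_cache$bundle))
    .bundle_cache$bundle <- simulate_bundle(sim_config(seed = 20260927L))
  .bundle_cache$bundle
}
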