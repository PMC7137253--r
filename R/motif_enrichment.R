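DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts are converted to per-position probabilities after adding a
#' pseudocount of `pseudocount_frac` times the column total to every cell
#' (avoids minus-infinity log-odds for unobserved bases).
#'
#' @param motif_id Motif identifier.
#' @param counts A 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param pseudocount_frac Fraction of the column total added to each cell
#'   (default 0.01).
#' @return An object of class `"pwm"`: `motif_id`, `counts`, `probs`
#'   (columns sum to 1), `length`.
#' @export
pwm <- function(motif_id, counts, pseudocount_frac = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L, all(counts >= 0),
            all(colSums(counts) > 0))
  rownames(counts) <- DNA_BASES
  probs <- apply(counts, 2L, function(col) {
    col <- col + pseudocount_frac * sum(col)
    col / sum(col)
  })
  rownames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id, counts = counts, probs = probs,
                 length = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  consensus <- paste(DNA_BASES[apply(x$probs, 2L, which.max)], collapse = "")
  cat("pwm [", x$motif_id, "]: length ", x$length,
      ", consensus ", consensus, "\n", sep = "")
  invisible(x)
}

#' Read PWMs from a TRANSFAC flat matrix file
#'
#' Parses the classic TRANSFAC layout: records separated by `//`, `ID` (or
#' `NA`/`AC` as fallback) naming the motif, a `P0  A C G T` header and
#' numbered count rows, ended by `XX`.
#'
#' @param path Path to the flat file.
#' @param pseudocount_frac Passed to [pwm()].
#' @return A named list of `"pwm"` objects.
#' @export
read_transfac <- function(path, pseudocount_frac = 0.01) {
  lines <- readLines(path)
  pwms <- list()
  id <- NULL; rows <- list(); in_matrix <- FALSE; col_order <- DNA_BASES
  flush <- function() {
    if (is.null(id) && length(rows) == 0L) return()
    if (is.null(id)) stop("TRANSFAC record without ID line")
    if (length(rows) == 0L)
      stop("TRANSFAC record without matrix rows: ", id)
    m <- do.call(cbind, rows)
    m <- m[match(DNA_BASES, col_order), , drop = FALSE]
    pwms[[id]] <<- pwm(id, m, pseudocount_frac = pseudocount_frac)
  }
  for (ln in lines) {
    if (grepl("^//", ln)) { flush(); id <- NULL; rows <- list(); next }
    if (grepl("^(ID|AC|NA)\\s", ln) && is.null(id)) {
      id <- sub("^\\S+\\s+", "", trimws(ln)); next
    }
    if (grepl("^P0", ln)) {
      col_order <- strsplit(trimws(sub("^P0\\s+", "", ln)), "\\s+")[[1L]]
      if (!setequal(col_order, DNA_BASES))
        stop("malformed P0 header in TRANSFAC record ",
             if (is.null(id)) "<unnamed>" else id)
      in_matrix <- TRUE; next
    }
    if (grepl("^XX", ln)) { in_matrix <- FALSE; next }
    if (in_matrix && grepl("^\\d+", ln)) {
      fields <- strsplit(trimws(ln), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (length(fields) < 5L || anyNA(vals))
        stop("malformed matrix row in TRANSFAC record ",
             if (is.null(id)) "<unnamed>" else id, ": ", ln)
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  if (length(pwms) == 0L) stop("no PWM records found in ", path)
  pwms
}

#' Write PWMs as a TRANSFAC flat matrix file
#'
#' @param pwms A list of `"pwm"` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("ID", p$motif_id),
                 sprintf("P0%7s%7s%7s%7s", "A", "C", "G", "T")), con)
    for (j in seq_len(p$length))
      writeLines(sprintf("%02d %12.6f %12.6f %12.6f %12.6f", j,
                         p$counts["A", j], p$counts["C", j],
                         p$counts["G", j], p$counts["T", j]), con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Genome mononucleotide background
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named A/C/G/T probability vector (N excluded).
#' @export
genome_background <- function(genome) {
  af <- Biostrings::alphabetFrequency(genome, collapse = TRUE)[DNA_BASES]
  af / sum(af)
}

#' Log-odds score matrix of a PWM against a background
#'
#' @param p A `"pwm"`.
#' @param background Named A/C/G/T probability vector.
#' @return 4 x L matrix of log2(p/background) scores (bits).
#' @export
pwm_logodds <- function(p, background) {
  stopifnot(inherits(p, "pwm"), setequal(names(background), DNA_BASES))
  background <- background[DNA_BASES] / sum(background)
  log2(p$probs / as.numeric(background))
}

#' Score threshold from the exact background score distribution
#'
#' The per-window log-odds score distribution under the (0-order) background
#' is enumerated exactly by convolution over motif positions on a discretized
#' score grid; the threshold is the smallest grid score whose tail
#' probability is at most `p_site`.
#'
#' @param p A `"pwm"`.
#' @param background Named A/C/G/T probability vector.
#' @param p_site Per-window p-value bound (default 1e-4).
#' @param granularity Score grid step in bits (default 0.01).
#' @return The score threshold in bits (`Inf` when not even the maximal score
#'   reaches the bound).
#' @export
score_threshold <- function(p, background, p_site = 1e-4,
                            granularity = 0.01) {
  lom <- pwm_logodds(p, background)
  grid <- round(lom / granularity)
  bg <- background[DNA_BASES] / sum(background)
  # dist[i] = P(integer score == cur_min + i - 1) after the columns seen so far
  dist <- 1
  cur_min <- 0L
  for (j in seq_len(ncol(grid))) {
    col_min <- min(grid[, j])
    col_max <- max(grid[, j])
    new_len <- length(dist) + (col_max - col_min)
    new <- numeric(new_len)
    for (b in seq_len(4L)) {
      sh <- grid[b, j] - col_min
      new[(1L + sh):(length(dist) + sh)] <-
        new[(1L + sh):(length(dist) + sh)] + dist * as.numeric(bg[b])
    }
    dist <- new
    cur_min <- cur_min + col_min
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p_site & dist > 0)   # smallest achievable score
  if (length(ok) == 0L) return(Inf)
  (cur_min + ok[1L] - 1L) * granularity
}

revcomp_pwm_matrix <- function(m) {
  m <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(m) <- DNA_BASES
  m
}

base_codes <- function(seq_char) {
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  codes <- lut[utf8ToInt(seq_char)]
  if (any(codes == 0L)) stop("sequence letter outside {A,C,G,T,N}")
  codes
}

scan_scores <- function(codes, lom) {
  L <- ncol(lom)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  lom5 <- rbind(lom, N = rep(-Inf, L))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    col <- unname(lom5[, j])
    sc <- sc + col[codes[j:(j + n - 1L)]]
  }
  sc
}

#' Scan a genome with PWMs
#'
#' Both strands of every scaffold are scanned with the log-odds matrix; a
#' window is reported when its score reaches the exact-distribution threshold
#' for `p_site` (see [score_threshold()]). Windows containing N are skipped.
#' Opposite-strand hits of the same motif at the same interval (palindromes)
#' are deduplicated to a single (plus-strand) occurrence; same-strand
#' overlapping hits at different offsets are all kept.
#'
#' @param pwms A `"pwm"` or list of `"pwm"` objects.
#' @param genome A [Biostrings::DNAStringSet].
#' @param p_site Per-window p-value bound (default 1e-4).
#' @param background Named A/C/G/T probabilities; defaults to the genome
#'   mononucleotide frequencies.
#' @param granularity Score grid step for the threshold (bits).
#' @return A [GenomicRanges::GRanges] of occurrences with strand and metadata
#'   columns `motif_id` and `score` (log-odds bits, on the discretization
#'   grid used for the threshold).
#' @export
scan_genome <- function(pwms, genome, p_site = 1e-4, background = NULL,
                        granularity = 0.01) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(background)) background <- genome_background(genome)
  codes_by_scaffold <- lapply(seq_along(genome), function(i)
    base_codes(as.character(genome[[i]])))
  names(codes_by_scaffold) <- names(genome)
  hits <- list()
  for (p in pwms) {
    thr <- score_threshold(p, background, p_site = p_site,
                           granularity = granularity)
    if (!is.finite(thr)) next
    thr_int <- round(thr / granularity)
    # score and select on the same discretized grid the threshold was
    # enumerated on, so the p-value guarantee is exact
    grid_fwd <- round(pwm_logodds(p, background) / granularity)
    grid_rev <- revcomp_pwm_matrix(grid_fwd)
    for (sc in names(genome)) {
      codes <- codes_by_scaffold[[sc]]
      for (str in c("+", "-")) {
        s <- scan_scores(codes, if (str == "+") grid_fwd else grid_rev)
        pass <- which(s >= thr_int)
        if (length(pass) == 0L) next
        hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
          seqnames = sc,
          ranges = IRanges::IRanges(pass, width = p$length),
          strand = str, motif_id = p$motif_id,
          score = s[pass] * granularity)
      }
    }
  }
  if (length(hits) == 0L)
    return(GenomicRanges::GRanges(motif_id = character(0),
                                  score = numeric(0)))
  occ <- unlist(GenomicRanges::GRangesList(hits))
  # palindromic dedup: same motif, same interval, both strands -> keep "+"
  key <- paste(occ$motif_id, as.character(GenomicRanges::seqnames(occ)),
               GenomicRanges::start(occ))
  ord <- order(key, as.character(GenomicRanges::strand(occ)))
  occ <- occ[ord]
  occ[!duplicated(paste(occ$motif_id,
                        as.character(GenomicRanges::seqnames(occ)),
                        GenomicRanges::start(occ)))]
}

#' Motif enrichment of a region set
#'
#' For each motif, E = OCC_obs / OCC_exp where OCC_obs is the number of
#' genome-wide occurrences overlapping the region set by at least 1 bp (each
#' occurrence counted at most once) and OCC_exp = N * L_r / L_g is the count
#' expected if the N genome occurrences fell uniformly (L_r: bases in the
#' region set after merging overlaps; L_g: genome size).
#'
#' @param occurrences [scan_genome()] output over the same genome.
#' @param regions The examined region set ([GenomicRanges::GRanges]).
#' @param genome The genome.
#' @return A data.frame with one row per motif: `motif_id`, `n_genome`,
#'   `occ_obs`, `occ_exp`, `enrichment`, `region_bases`, `genome_bases`,
#'   `undefined` (TRUE when N = 0 leaves E undefined).
#' @export
motif_enrichment <- function(occurrences, regions, genome) {
  merged <- GenomicRanges::reduce(GenomicRanges::granges(regions),
                                  ignore.strand = TRUE)
  l_r <- sum(as.numeric(GenomicRanges::width(merged)))
  if (l_r == 0) stop("empty region set (L_r = 0)")
  l_g <- genome_length(genome)
  ids <- unique(occurrences$motif_id)
  rows <- lapply(ids, function(id) {
    occ <- occurrences[occurrences$motif_id == id]
    n <- length(occ)
    obs <- sum(GenomicRanges::countOverlaps(occ, merged,
                                            ignore.strand = TRUE) > 0L)
    expd <- n * l_r / l_g
    data.frame(motif_id = id, n_genome = n, occ_obs = obs, occ_exp = expd,
               enrichment = if (n > 0L) obs / expd else NA_real_,
               region_bases = l_r, genome_bases = l_g,
               undefined = n == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair motif enrichments from two region sets
#'
#' @param results_a,results_b [motif_enrichment()] tables sharing motif ids.
#' @return A list: `table` (one row per shared motif with `enrichment_a`,
#'   `enrichment_b`) and `r`, their Pearson correlation.
#' @export
enrichment_scatter <- function(results_a, results_b) {
  shared <- intersect(results_a$motif_id, results_b$motif_id)
  if (length(shared) == 0L) stop("no shared motif ids")
  a <- results_a[match(shared, results_a$motif_id), ]
  b <- results_b[match(shared, results_b$motif_id), ]
  tab <- data.frame(motif_id = shared,
                    enrichment_a = a$enrichment,
                    enrichment_b = b$enrichment,
                    stringsAsFactors = FALSE)
  list(table = tab,
       r = if (nrow(tab) >= 3L) correlate(tab$enrichment_a, tab$enrichment_b)
           else NA_real_)
}
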