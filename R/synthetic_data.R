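#' Simulation configuration
#'
#' Defaults emulate the genome-wide conditions the pipeline is designed for:
#' a multi-scaffold genome with Xenopus-like base composition (A/T near 30%,
#' C/G near 20%), genes with a geometric intron-count distribution of mean
#' 7.8, sisRNAs at an average rate of 0.36 per intron with mean length near
#' 360 bp, planted composition bias (GC up by ~1.9 percentage points, CpG
#' down and CA/TG up via deamination-style CG rewriting), positional bias
#' toward first and especially last introns, planted motif sites at a
#' configurable fold inside sisRNAs, decoy peaks that violate each
#' classification rule, a conservation track elevated on exons with ramps at
#' intron boundaries, and peak signals negatively coupled to host-gene FPKM.
#'
#' @param seed Root seed; the whole bundle is a deterministic function of it.
#' @param n_scaffolds,scaffold_length Genome shape.
#' @param n_genes Number of genes packed onto the scaffolds.
#' @param base_freqs Background base probabilities (named A/C/G/T).
#' @param intron_count_mean Mean of the geometric intron-count distribution
#'   (0 introns allowed: single-exon genes).
#' @param exon_length_meanlog,exon_length_sdlog,exon_length_min Log-normal
#'   exon lengths (bp).
#' @param intron_length_meanlog,intron_length_sdlog,intron_length_min
#'   Log-normal intron lengths (bp).
#' @param sisrna_rate_per_intron Average planted sisRNAs per intron; the
#'   per-intron rate scales with intron length (longer introns host more
#'   sisRNAs) and with the positional multipliers.
#' @param sisrna_length_meanlog,sisrna_length_sdlog,sisrna_length_min
#'   Log-normal sisRNA lengths, truncated to `[sisrna_length_min,
#'   intron length - 2]`.
#' @param delta_gc Target pooled GC excess of planted sisRNA sequence over
#'   the genome background (fraction).
#' @param cpg_rewrite_frac Fraction of CG dinucleotides inside planted
#'   regions rewritten to TG or CA (lowers CpG, raises CA|TG; the GC shift is
#'   compensated so `delta_gc` is still realized).
#' @param first_intron_bias,positional_bias Rate multipliers for the first
#'   and last intron of a gene.
#' @param motif_consensus Planted motif consensus (GC-balanced by default).
#' @param motif_site_rate Background planted-site rate per base pair outside
#'   sisRNAs.
#' @param motif_fold Fold elevation of the site rate inside planted sisRNAs.
#' @param decoy_exon_rate,decoy_short_rate,decoy_intergenic_rate Decoy peak
#'   counts as fractions of the planted sisRNA count: peaks crossing an exon
#'   boundary, fully intronic peaks shorter than 150 bp, and peaks outside
#'   genes.
#' @param cons_exon_level,cons_intron_level,cons_ramp,cons_noise_sd
#'   Conservation track: exon and intron/intergenic score levels, linear ramp
#'   width (bp) inside each intron end, Gaussian noise SD (clamped to [0,1]).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal host-gene expression.
#' @param fpkm_coupling Exponent of the negative signal-FPKM coupling
#'   (planted peak signal is proportional to `fpkm^-fpkm_coupling` times
#'   log-normal noise).
#' @param signal_base,signal_noise_sd Peak signal scale and log-noise SD.
#' @param min_gap,max_gap Intergenic gap range (uniform, bp).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 4L,
                       scaffold_length = 700000L,
                       n_genes = 200L,
                       base_freqs = c(A = 0.2997, C = 0.2004,
                                      G = 0.2004, T = 0.2996),
                       intron_count_mean = 7.8,
                       exon_length_meanlog = log(250),
                       exon_length_sdlog = 0.35,
                       exon_length_min = 160L,
                       intron_length_meanlog = log(700),
                       intron_length_sdlog = 0.7,
                       intron_length_min = 180L,
                       sisrna_rate_per_intron = 0.36,
                       sisrna_length_meanlog = log(330),
                       sisrna_length_sdlog = 0.45,
                       sisrna_length_min = 150L,
                       delta_gc = 0.0185,
                       cpg_rewrite_frac = 0.5,
                       first_intron_bias = 2,
                       positional_bias = 3,
                       motif_consensus = "TGACTGCA",
                       motif_site_rate = 1.5e-4,
                       motif_fold = 2,
                       decoy_exon_rate = 0.4,
                       decoy_short_rate = 0.15,
                       decoy_intergenic_rate = 0.6,
                       cons_exon_level = 0.8,
                       cons_intron_level = 0.25,
                       cons_ramp = 10L,
                       cons_noise_sd = 0.05,
                       fpkm_meanlog = log(10),
                       fpkm_sdlog = 1,
                       fpkm_coupling = 0.3,
                       signal_base = 50,
                       signal_noise_sd = 0.6,
                       min_gap = 500L,
                       max_gap = 2500L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_scaffolds >= 1L, cfg$scaffold_length > 0L, cfg$n_genes >= 1L,
            abs(sum(cfg$base_freqs) - 1) < 0.01,
            setequal(names(cfg$base_freqs), c("A", "C", "G", "T")),
            cfg$sisrna_rate_per_intron >= 0,
            cfg$cpg_rewrite_frac >= 0, cfg$cpg_rewrite_frac <= 1,
            cfg$delta_gc > -0.2, cfg$delta_gc < 0.2,
            cfg$motif_fold >= 0,
            cfg$decoy_exon_rate >= 0, cfg$decoy_short_rate >= 0,
            cfg$decoy_intergenic_rate >= 0,
            cfg$cons_exon_level >= 0, cfg$cons_exon_level <= 1,
            cfg$cons_intron_level >= 0, cfg$cons_intron_level <= 1,
            cfg$sisrna_length_min > 0, cfg$min_gap >= 0,
            cfg$max_gap >= cfg$min_gap)
  cfg$base_freqs <- cfg$base_freqs[c("A", "C", "G", "T")] /
    sum(cfg$base_freqs)
  structure(cfg, class = "sim_config")
}

random_letters <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

rlnorm_min <- function(n, meanlog, sdlog, min_val) {
  pmax(round(stats::rlnorm(n, meanlog, sdlog)), min_val)
}

# Base frequencies for planted regions: pre-rewrite GC level x solves
# x - r * (x/2)^2 = target (rewriting a fraction r of CG dinucleotides
# removes one G or C each; CG frequency under the 0-order model is
# (x/2)^2 per offset).
planted_base_freqs <- function(cfg) {
  g_target <- unname(cfg$base_freqs[["C"]] + cfg$base_freqs[["G"]]) +
    cfg$delta_gc
  r <- cfg$cpg_rewrite_frac
  x <- if (r > 0) (1 - sqrt(1 - r * g_target)) * 2 / r else g_target
  c(A = (1 - x) / 2, C = x / 2, G = x / 2, T = (1 - x) / 2)
}

# Draw a biased sequence for one planted region and apply the CG rewrite.
planted_seq <- function(len, cfg, freqs) {
  chars <- random_letters(len, freqs)
  if (cfg$cpg_rewrite_frac > 0 && len >= 2L) {
    is_cg <- which(chars[-len] == "C" & chars[-1L] == "G")
    rewrite <- is_cg[stats::runif(length(is_cg)) < cfg$cpg_rewrite_frac]
    if (length(rewrite) > 0L) {
      to_tg <- stats::runif(length(rewrite)) < 0.5
      chars[rewrite[to_tg]] <- "T"              # CG -> TG
      chars[rewrite[!to_tg] + 1L] <- "A"        # CG -> CA
    }
  }
  chars
}

#' Generate a synthetic genome bundle with planted ground truth
#'
#' Produces, deterministically from `config$seed`, a genome, merged gene
#' models, an RNA peak set (planted sisRNAs plus decoys), a conservation
#' track, PWMs (the planted motif and one never-planted control), a per-gene
#' FPKM table, and the ground truth of everything planted.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_bundle"`: `genome`
#'   ([Biostrings::DNAStringSet]), `genes` ([GenomicRanges::GRangesList]),
#'   `introns`, `peaks`, `track`, `pwms`, `fpkm`, `truth` (list with
#'   `sisrnas`, `motif_sites`, `realized` composition deltas) and `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## --- gene structures -----------------------------------------------------
  n_introns <- stats::rgeom(cfg$n_genes, prob = 1 / (1 + cfg$intron_count_mean))
  exon_lens <- lapply(n_introns + 1L, function(k)
    rlnorm_min(k, cfg$exon_length_meanlog, cfg$exon_length_sdlog,
               cfg$exon_length_min))
  intron_lens <- lapply(n_introns, function(k)
    if (k == 0L) integer(0) else
      rlnorm_min(k, cfg$intron_length_meanlog, cfg$intron_length_sdlog,
                 cfg$intron_length_min))
  spans <- mapply(function(e, i) sum(e) + sum(i), exon_lens, intron_lens)
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gaps <- round(stats::runif(cfg$n_genes, cfg$min_gap, cfg$max_gap))
  if (sum(spans) + sum(gaps) >
      cfg$n_scaffolds * (cfg$scaffold_length - 2L * cfg$max_gap))
    stop("infeasible packing: genes exceed scaffold capacity")

  ## --- pack genes onto scaffolds ------------------------------------------
  gene_scaffold <- character(cfg$n_genes)
  gene_start <- integer(cfg$n_genes)
  sc_names <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
  sc_idx <- 1L
  cursor <- cfg$min_gap
  for (i in seq_len(cfg$n_genes)) {
    if (cursor + gaps[i] + spans[i] + cfg$min_gap > cfg$scaffold_length) {
      sc_idx <- sc_idx + 1L
      if (sc_idx > cfg$n_scaffolds)
        stop("infeasible packing: genes exceed scaffold capacity")
      cursor <- cfg$min_gap
    }
    gene_scaffold[i] <- sc_names[sc_idx]
    gene_start[i] <- cursor + gaps[i] + 1L
    cursor <- cursor + gaps[i] + spans[i]
  }

  ## --- exon coordinates ----------------------------------------------------
  gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_genes))
  exon_rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    e <- exon_lens[[i]]; it <- intron_lens[[i]]
    piece <- integer(0)
    for (k in seq_along(e)) {
      piece <- c(piece, e[k], if (k <= length(it)) it[k] else integer(0))
    }
    bounds <- cumsum(c(0L, piece))
    starts <- gene_start[i] + bounds[seq(1L, length(piece), by = 2L)]
    ends <- starts + e - 1L
    exon_rows[[i]] <- data.frame(scaffold = gene_scaffold[i],
                                 start = starts, end = ends,
                                 strand = strands[i], gene_id = gene_ids[i],
                                 stringsAsFactors = FALSE)
  }
  exon_df <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges(exon_df$scaffold,
                                  IRanges::IRanges(exon_df$start, exon_df$end),
                                  strand = exon_df$strand,
                                  gene_id = exon_df$gene_id)
  genes <- gene_models_from_exons(exons)
  genes <- genes[gene_ids]  # stable order
  introns <- derive_introns(genes)
  introns <- classify_intron_position(introns)

  ## --- background genome ---------------------------------------------------
  scaffold_chars <- lapply(sc_names, function(s)
    random_letters(cfg$scaffold_length, cfg$base_freqs))
  names(scaffold_chars) <- sc_names

  ## --- plant sisRNAs -------------------------------------------------------
  n_per_gene <- as.integer(table(factor(introns$gene_id, levels = gene_ids)))
  names(n_per_gene) <- gene_ids
  iw <- GenomicRanges::width(introns)
  mult <- rep(1, length(introns))
  n_i <- n_per_gene[introns$gene_id]
  mult[introns$ordinal == 1L & n_i > 1L] <- cfg$first_intron_bias
  mult[introns$ordinal == n_i & n_i > 1L] <- cfg$positional_bias
  w <- (iw / mean(iw)) * mult
  lambda <- cfg$sisrna_rate_per_intron * w / mean(w)
  n_sis <- stats::rpois(length(introns), lambda)

  freqs_planted <- planted_base_freqs(cfg)
  sis_rows <- vector("list", sum(n_sis))
  row_i <- 0L
  for (ii in which(n_sis > 0L)) {
    s0 <- GenomicRanges::start(introns)[ii]
    e0 <- GenomicRanges::end(introns)[ii]
    placed <- IRanges::IRanges()
    for (rep_k in seq_len(n_sis[ii])) {
      len <- rlnorm_min(1L, cfg$sisrna_length_meanlog, cfg$sisrna_length_sdlog,
                        cfg$sisrna_length_min)
      max_len <- e0 - s0 - 1L          # keep 1 bp clear of each boundary
      if (max_len < cfg$sisrna_length_min) next
      len <- min(len, max_len)
      ok <- FALSE
      for (try_k in 1:25) {
        st <- s0 + sample.int(e0 - len - s0, 1L)   # st in [s0+1, e0-len]
        cand <- IRanges::IRanges(st, st + len - 1L)
        if (length(placed) == 0L ||
            sum(IRanges::countOverlaps(cand, placed)) == 0L) {
          placed <- c(placed, cand); ok <- TRUE; break
        }
      }
      if (!ok) next
      row_i <- row_i + 1L
      sis_rows[[row_i]] <- data.frame(
        scaffold = as.character(GenomicRanges::seqnames(introns))[ii],
        start = st, end = st + len - 1L,
        gene_id = introns$gene_id[ii], ordinal = introns$ordinal[ii],
        stringsAsFactors = FALSE)
    }
  }
  sis_df <- do.call(rbind, sis_rows[seq_len(row_i)])
  if (is.null(sis_df) || nrow(sis_df) == 0L)
    stop("no sisRNAs could be planted under this configuration")
  # biased sequence inside each planted region
  for (i in seq_len(nrow(sis_df))) {
    len <- sis_df$end[i] - sis_df$start[i] + 1L
    scaffold_chars[[sis_df$scaffold[i]]][sis_df$start[i]:sis_df$end[i]] <-
      planted_seq(len, cfg, freqs_planted)
  }

  ## --- plant motif sites ---------------------------------------------------
  consensus <- toupper(cfg$motif_consensus)
  mlen <- nchar(consensus)
  l_g <- as.numeric(cfg$n_scaffolds) * cfg$scaffold_length
  l_r <- sum(sis_df$end - sis_df$start + 1)
  sis_ir_by_sc <- split(IRanges::IRanges(sis_df$start, sis_df$end),
                        sis_df$scaffold)
  site_rows <- list()
  put_site <- function(scaffold, start, inside) {
    seq_chars <- strsplit(consensus, "")[[1L]]
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-")
      seq_chars <- rev(c(A = "T", C = "G", G = "C", T = "A")[seq_chars])
    scaffold_chars[[scaffold]][start:(start + mlen - 1L)] <<- seq_chars
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      scaffold = scaffold, start = start, end = start + mlen - 1L,
      strand = strand, inside_sisrna = inside, stringsAsFactors = FALSE)
  }
  n_out <- stats::rpois(1L, cfg$motif_site_rate * (l_g - l_r))
  for (k in seq_len(n_out)) {
    for (try_k in 1:20) {
      scf <- sample(sc_names, 1L)
      st <- sample.int(cfg$scaffold_length - mlen, 1L)
      cand <- IRanges::IRanges(st, st + mlen - 1L)
      sis_here <- sis_ir_by_sc[[scf]]
      clash <- !is.null(sis_here) &&
        sum(IRanges::countOverlaps(cand, sis_here)) > 0L
      if (!clash) { put_site(scf, st, FALSE); break }
    }
  }
  n_in <- stats::rpois(1L, cfg$motif_fold * cfg$motif_site_rate * l_r)
  sis_w <- sis_df$end - sis_df$start + 1L
  eligible <- which(sis_w >= mlen + 2L)
  for (k in seq_len(n_in)) {
    if (length(eligible) == 0L) break
    i <- eligible[sample.int(length(eligible), 1L,
                             prob = sis_w[eligible])]
    st <- sis_df$start[i] + sample.int(sis_w[i] - mlen, 1L) - 1L
    put_site(sis_df$scaffold[i], st, TRUE)
  }
  site_df <- if (length(site_rows) > 0L) do.call(rbind, site_rows) else NULL

  ## --- finalize genome -----------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(scaffold_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- sc_names

  ## --- conservation track --------------------------------------------------
  track_scores <- lapply(sc_names, function(s)
    rep(cfg$cons_intron_level, cfg$scaffold_length))
  names(track_scores) <- sc_names
  for (i in seq_along(exons)) {
    scf <- as.character(GenomicRanges::seqnames(exons))[i]
    track_scores[[scf]][GenomicRanges::start(exons)[i]:
                          GenomicRanges::end(exons)[i]] <- cfg$cons_exon_level
  }
  if (cfg$cons_ramp > 0L) {
    ramp_down <- seq(cfg$cons_exon_level, cfg$cons_intron_level,
                     length.out = cfg$cons_ramp + 2L)[-1L]
    ramp_down <- ramp_down[-length(ramp_down)]
    for (i in seq_along(introns)) {
      scf <- as.character(GenomicRanges::seqnames(introns))[i]
      s0 <- GenomicRanges::start(introns)[i]
      e0 <- GenomicRanges::end(introns)[i]
      if (e0 - s0 + 1L >= 2L * cfg$cons_ramp + 2L) {
        track_scores[[scf]][s0:(s0 + cfg$cons_ramp - 1L)] <- ramp_down
        track_scores[[scf]][e0:(e0 - cfg$cons_ramp + 1L)] <- ramp_down
      }
    }
  }
  if (cfg$cons_noise_sd > 0) {
    track_scores <- lapply(track_scores, function(v)
      pmin(pmax(v + stats::rnorm(length(v), 0, cfg$cons_noise_sd), 0), 1))
  }
  track_scores <- lapply(track_scores, round, digits = 3L)
  track <- conservation_track(track_scores)

  ## --- expression and peak signals -----------------------------------------
  fpkm <- data.frame(gene_id = gene_ids,
                     fpkm = stats::rlnorm(cfg$n_genes, cfg$fpkm_meanlog,
                                          cfg$fpkm_sdlog),
                     stringsAsFactors = FALSE)
  host_fpkm <- fpkm$fpkm[match(sis_df$gene_id, fpkm$gene_id)]
  sis_signal <- cfg$signal_base *
    (host_fpkm / exp(cfg$fpkm_meanlog))^(-cfg$fpkm_coupling) *
    stats::rlnorm(nrow(sis_df), 0, cfg$signal_noise_sd)

  ## --- decoy peaks ----------------------------------------------------------
  decoy_rows <- list()
  n_planted <- nrow(sis_df)
  exon_b <- data.frame(scaffold = as.character(GenomicRanges::seqnames(exons)),
                       start = GenomicRanges::start(exons),
                       end = GenomicRanges::end(exons),
                       stringsAsFactors = FALSE)
  n_exon_decoy <- round(cfg$decoy_exon_rate * n_planted)
  if (n_exon_decoy > 0L) {
    pick <- sample.int(nrow(exon_b), n_exon_decoy, replace = TRUE)
    left <- stats::runif(n_exon_decoy) < 0.5
    bnd <- ifelse(left, exon_b$start[pick], exon_b$end[pick])
    u1 <- round(stats::runif(n_exon_decoy, 80, 200))
    u2 <- round(stats::runif(n_exon_decoy, 80, 200))
    st <- pmax(bnd - u1, 1L)
    en <- pmin(bnd + u2, cfg$scaffold_length)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      scaffold = exon_b$scaffold[pick], start = st, end = en,
      kind = "exon_crossing", stringsAsFactors = FALSE)
  }
  n_short <- round(cfg$decoy_short_rate * n_planted)
  big_introns <- which(iw >= 160L)
  if (n_short > 0L && length(big_introns) > 0L) {
    pick <- sample(big_introns, n_short, replace = TRUE)
    len <- round(stats::runif(n_short, 60, 149))
    s0 <- GenomicRanges::start(introns)[pick]
    e0 <- GenomicRanges::end(introns)[pick]
    st <- s0 + vapply(e0 - len - s0, function(m) sample.int(m, 1L), integer(1))
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(introns))[pick],
      start = st, end = st + len - 1L,
      kind = "short", stringsAsFactors = FALSE)
  }
  n_inter <- round(cfg$decoy_intergenic_rate * n_planted)
  if (n_inter > 0L) {
    gene_span <- unlist(range(genes), use.names = FALSE)
    span_by_sc <- split(IRanges::IRanges(GenomicRanges::start(gene_span),
                                         GenomicRanges::end(gene_span)),
                        as.character(GenomicRanges::seqnames(gene_span)))
    got <- 0L
    attempts <- 0L
    while (got < n_inter && attempts < 100L * n_inter) {
      attempts <- attempts + 1L
      scf <- sample(sc_names, 1L)
      len <- rlnorm_min(1L, cfg$sisrna_length_meanlog,
                        cfg$sisrna_length_sdlog, cfg$sisrna_length_min)
      if (len + 2L >= cfg$scaffold_length) next
      st <- sample.int(cfg$scaffold_length - len, 1L)
      cand <- IRanges::IRanges(st, st + len - 1L)
      spans_here <- span_by_sc[[scf]]
      if (!is.null(spans_here) &&
          sum(IRanges::countOverlaps(cand, spans_here)) > 0L) next
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        scaffold = scf, start = st, end = st + len - 1L,
        kind = "intergenic", stringsAsFactors = FALSE)
      got <- got + 1L
    }
  }
  decoy_df <- if (length(decoy_rows) > 0L) do.call(rbind, decoy_rows) else NULL

  ## --- assemble peak set ----------------------------------------------------
  peak_df <- data.frame(scaffold = sis_df$scaffold, start = sis_df$start,
                        end = sis_df$end, signal = sis_signal,
                        is_sisrna = TRUE, stringsAsFactors = FALSE)
  if (!is.null(decoy_df)) {
    peak_df <- rbind(peak_df,
                     data.frame(scaffold = decoy_df$scaffold,
                                start = decoy_df$start, end = decoy_df$end,
                                signal = cfg$signal_base *
                                  stats::rlnorm(nrow(decoy_df), 0,
                                                cfg$signal_noise_sd),
                                is_sisrna = FALSE, stringsAsFactors = FALSE))
  }
  ord <- sample.int(nrow(peak_df))
  peak_df <- peak_df[ord, ]
  peak_df$name <- sprintf("peak_%05d", seq_len(nrow(peak_df)))
  width <- peak_df$end - peak_df$start + 1L
  peaks <- GenomicRanges::GRanges(
    peak_df$scaffold, IRanges::IRanges(peak_df$start, peak_df$end),
    name = peak_df$name, signal = peak_df$signal,
    summit = vapply(width, function(wd) sample.int(wd, 1L), integer(1)),
    fdr = stats::runif(nrow(peak_df), 0, 0.01))

  ## --- PWMs -----------------------------------------------------------------
  consensus_pwm <- function(id, word, major = 0.85) {
    bases <- strsplit(word, "")[[1L]]
    m <- matrix((1 - major) / 3 * 100, nrow = 4L, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
    m[cbind(match(bases, DNA_BASES), seq_along(bases))] <- major * 100
    pwm(id, m)
  }
  pwms <- list(planted = consensus_pwm("planted_motif", consensus),
               control = consensus_pwm("control_motif", "ACGTAGTC"))

  ## --- ground truth ----------------------------------------------------------
  truth_sis <- GenomicRanges::GRanges(
    sis_df$scaffold, IRanges::IRanges(sis_df$start, sis_df$end),
    gene_id = sis_df$gene_id, intron_ordinal = sis_df$ordinal)
  truth_sites <- if (!is.null(site_df))
    GenomicRanges::GRanges(site_df$scaffold,
                           IRanges::IRanges(site_df$start, site_df$end),
                           strand = site_df$strand,
                           inside_sisrna = site_df$inside_sisrna)
  else GenomicRanges::GRanges()
  planted_comp <- base_composition(truth_sis, genome, "planted")
  genome_comp <- base_composition(whole_genome_regions(genome), genome,
                                  "genome")
  planted_seqs <- region_seqs(truth_sis, genome)
  genome_seqs <- genome
  realized <- list(
    delta_gc = planted_comp$gc_fraction - genome_comp$gc_fraction,
    delta_cpg = dinucleotide_density(planted_seqs, class = "CG") -
      dinucleotide_density(genome_seqs, class = "CG"),
    delta_catg = dinucleotide_density(planted_seqs, class = "CA|TG") -
      dinucleotide_density(genome_seqs, class = "CA|TG"))

  structure(list(genome = genome, genes = genes, introns = introns,
                 peaks = peaks, track = track, pwms = pwms, fpkm = fpkm,
                 truth = list(sisrnas = truth_sis, motif_sites = truth_sites,
                              realized = realized),
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle: ", length(x$genome), " scaffold(s), ",
      format(genome_length(x$genome), big.mark = ","), " bp, ",
      length(x$genes), " gene(s), ", length(x$peaks), " peak(s) (",
      length(x$truth$sisrnas), " planted sisRNA(s))\n", sep = "")
  invisible(x)
}

#' Write a bundle to standard-format files
#'
#' Emits genome.fa, genes.genePred, peaks.bed, conservation.wig,
#' motifs.transfac, fpkm.tsv, plus the ground truth as
#' truth_sisrnas.tsv and truth_motif_sites.tsv. On a partial write the
#' already-written files are removed before the error propagates.
#'
#' @param bundle A `"sim_bundle"`.
#' @param dir Output directory (created if missing).
#' @return A manifest data.frame (`file`, `md5`), invisibly the same files on
#'   disk.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(genome = "genome.fa", genes = "genes.genePred",
             peaks = "peaks.bed", track = "conservation.wig",
             pwms = "motifs.transfac", fpkm = "fpkm.tsv",
             truth_sis = "truth_sisrnas.tsv",
             truth_sites = "truth_motif_sites.tsv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  written <- character(0)
  tryCatch({
    Biostrings::writeXStringSet(bundle$genome, paths["genome"])
    written <- c(written, paths["genome"])
    write_genepred(bundle$genes, paths["genes"])
    written <- c(written, paths["genes"])
    write_peaks(bundle$peaks, paths["peaks"])
    written <- c(written, paths["peaks"])
    write_conservation(bundle$track, paths["track"])
    written <- c(written, paths["track"])
    write_transfac(bundle$pwms, paths["pwms"])
    written <- c(written, paths["pwms"])
    utils::write.table(bundle$fpkm, paths["fpkm"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, paths["fpkm"])
    ts <- bundle$truth$sisrnas
    utils::write.table(
      data.frame(scaffold = as.character(GenomicRanges::seqnames(ts)),
                 start = GenomicRanges::start(ts) - 1L,
                 end = GenomicRanges::end(ts),
                 gene_id = ts$gene_id, intron_ordinal = ts$intron_ordinal),
      paths["truth_sis"], sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, paths["truth_sis"])
    ms <- bundle$truth$motif_sites
    utils::write.table(
      data.frame(scaffold = as.character(GenomicRanges::seqnames(ms)),
                 start = GenomicRanges::start(ms) - 1L,
                 end = GenomicRanges::end(ms),
                 strand = as.character(GenomicRanges::strand(ms)),
                 inside_sisrna = ms$inside_sisrna),
      paths["truth_sites"], sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, paths["truth_sites"])
  }, error = function(e) {
    unlink(written)
    stop("partial bundle write cleaned up: ", conditionMessage(e))
  })
  data.frame(file = unname(files),
             md5 = unname(tools::md5sum(paths)),
             row.names = NULL, stringsAsFactors = FALSE)
}
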