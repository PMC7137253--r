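test_that("FASTA loading normalizes case, keys by first header token, sums lengths", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1 description here", "acgt", ">s2", "ACGTACGTAC", "ACGTA"), fa)
  g <- load_genome(fa)
  expect_equal(names(g), c("s1", "s2"))
  expect_equal(as.character(g[["s1"]]), "ACGT")
  expect_equal(genome_length(g), 4 + 15)

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s1", "GGCC"), dup)
  expect_error(load_genome(dup), "duplicate")

  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(load_genome(empty))
})

test_that("genePred loading merges isoform exons into a per-gene union", {
  gp <- tempfile(fileext = ".gp")
  # two isoforms of geneA: (0,100)+(200,300) and (0,150)+(200,300) in
  # 0-based half-open -> union (1,150)+(201,300) 1-based closed
  writeLines(c(
    paste("geneA", "s1", "+", 0, 300, 0, 300, 2, "0,200,", "100,300,", sep = "\t"),
    paste("geneA", "s1", "+", 0, 300, 0, 300, 2, "0,200,", "150,300,", sep = "\t"),
    paste("geneB", "s1", "-", 400, 700, 400, 700, 2, "400,600,", "500,700,", sep = "\t")),
    gp)
  genes <- load_gene_models(gp, "genepred")
  expect_equal(sort(names(genes)), c("geneA", "geneB"))
  a <- genes[["geneA"]]
  expect_equal(start(a), c(1L, 201L))
  expect_equal(end(a), c(150L, 300L))
  expect_equal(unname(gene_strand(genes)[c("geneA", "geneB")]), c("+", "-"))

  bad <- tempfile(fileext = ".gp")
  writeLines(paste("g", "s1", "?", 0, 10, 0, 10, 1, "0,", "10,", sep = "\t"), bad)
  expect_error(load_gene_models(bad, "genepred"), "strand")
})

test_that("exon bounds are validated against the genome when provided", {
  genome <- make_genome(s1 = "ACGTACGTAC")
  ex <- GRanges("s1", IRanges(5, 20), strand = "+", gene_id = "g")
  expect_error(gene_models_from_exons(ex, genome), "bounds")
  ex2 <- GRanges("s2", IRanges(1, 4), strand = "+", gene_id = "g")
  expect_error(gene_models_from_exons(ex2, genome), "absent")
})

test_that("multi-isoform exon union equals the per-base boolean union", {
  set.seed(42)
  for (rep_i in 1:10) {
    n_iso <- 3
    exon_rows <- do.call(rbind, lapply(seq_len(n_iso), function(k) {
      n_ex <- sample(2:5, 1)
      s <- sort(sample.int(900, n_ex))
      w <- sample(10:60, n_ex, replace = TRUE)
      data.frame(start = s, end = s + w)
    }))
    gr <- GRanges("s1", IRanges(exon_rows$start, exon_rows$end),
                  strand = "+", gene_id = "g")
    merged <- gene_models_from_exons(gr)[["g"]]
    mask <- logical(1200)
    for (i in seq_len(nrow(exon_rows)))
      mask[exon_rows$start[i]:exon_rows$end[i]] <- TRUE
    merged_mask <- logical(1200)
    for (i in seq_along(merged))
      merged_mask[start(merged)[i]:end(merged)[i]] <- TRUE
    expect_identical(merged_mask, mask)
  }
})

test_that("introns are the gaps between merged exons with strand-aware ordinals", {
  genes <- make_genes(list(
    plus = list(scaffold = "s1", strand = "+",
                exons = cbind(c(1, 201), c(100, 300))),
    minus = list(scaffold = "s1", strand = "-",
                 exons = cbind(c(1001, 1201, 1401), c(1100, 1300, 1500))),
    single = list(scaffold = "s1", strand = "+",
                  exons = cbind(2001, 2100))))
  introns <- derive_introns(genes)
  p <- introns[introns$gene_id == "plus"]
  expect_equal(start(p), 101L)
  expect_equal(end(p), 200L)
  expect_equal(p$ordinal, 1L)
  m <- introns[introns$gene_id == "minus"]
  # minus strand: ordinal 1 is the rightmost gap
  expect_equal(start(m[m$ordinal == 1L]), 1301L)
  expect_equal(end(m[m$ordinal == 1L]), 1400L)
  expect_equal(start(m[m$ordinal == 2L]), 1101L)
  expect_equal(sum(introns$gene_id == "single"), 0L)
})

test_that("intron ordinals agree with sorting gaps by strand-aware 5' distance", {
  set.seed(7)
  for (rep_i in 1:8) {
    n_ex <- 8
    s <- cumsum(sample(50:300, 2 * n_ex - 1)) + 1000L
    starts <- s[seq(1, 2 * n_ex - 1, by = 2)]
    ends <- c(s[seq(2, 2 * n_ex - 1, by = 2)] - 1L, s[2 * n_ex - 1] + 80L)
    str <- sample(c("+", "-"), 1)
    genes <- make_genes(list(g = list(scaffold = "s1", strand = str,
                                      exons = cbind(starts, ends))))
    introns <- derive_introns(genes)
    # oracle: 5' distance of each gap midpoint
    mid <- (start(introns) + end(introns)) / 2
    dist5 <- if (str == "+") mid else -mid
    expect_equal(introns$ordinal, rank(dist5))
  }
})

test_that("exons and introns tile the gene span exactly", {
  inst <- random_instance(3, n_genes = 6, n_peaks = 1)
  genes <- inst$genes
  introns <- derive_introns(genes)
  for (g in names(genes)) {
    ex <- genes[[g]]
    itr <- introns[introns$gene_id == g]
    span <- max(end(ex)) - min(start(ex)) + 1L
    expect_equal(sum(width(ex)) + sum(width(itr)), span)
    # no overlap between exons and introns
    expect_equal(sum(countOverlaps(itr, ex)), 0L)
  }
})

test_that("S/M/E classification requires more than 3 introns", {
  mk <- function(n_introns, strand = "+") {
    n_ex <- n_introns + 1
    starts <- seq(1, by = 200, length.out = n_ex)
    make_genes(list(g = list(scaffold = "s1", strand = strand,
                             exons = cbind(starts, starts + 99))))
  }
  cls5 <- classify_intron_position(derive_introns(mk(5)))
  expect_equal(cls5$position_class[order(cls5$ordinal)],
               c("S", "M", "M", "M", "E"))
  cls4 <- classify_intron_position(derive_introns(mk(4, "-")))
  expect_equal(cls4$position_class[order(cls4$ordinal)],
               c("S", "M", "M", "E"))
  cls3 <- classify_intron_position(derive_introns(mk(3)))
  expect_true(all(cls3$position_class == "unclassified"))
})

test_that("conservation loading replays fixedStep and bedGraph records per base", {
  genome <- random_genome(c(s1 = 60, s2 = 40), seed = 5)
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=s1 start=1 step=1", "0.5", "0.5",
               "fixedStep chrom=s1 start=11 step=1", "0.25", "0.75"), wig)
  tr <- load_conservation(wig, genome)
  expect_equal(tr$scores$s1[1:2], c(0.5, 0.5))
  expect_true(all(is.na(tr$scores$s1[3:10])))
  expect_equal(tr$scores$s1[11:12], c(0.25, 0.75))
  expect_equal(length(tr$scores$s2), 40L)
  expect_true(all(is.na(tr$scores$s2)))

  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("s1\t0\t10\t1.0", "s2\t5\t8\t0.3"), bg)
  tr2 <- load_conservation(bg, genome)
  expect_equal(tr2$scores$s1[1:10], rep(1, 10))
  expect_true(is.na(tr2$scores$s1[11]))
  expect_equal(tr2$scores$s2[6:8], rep(0.3, 3))

  # mixed-coverage record replay oracle
  set.seed(9)
  n_rec <- 30
  starts <- sample.int(50, n_rec, replace = TRUE)
  widths <- sample(1:5, n_rec, replace = TRUE)
  vals <- round(runif(n_rec), 3)
  lines <- unlist(lapply(seq_len(n_rec), function(i)
    paste("s1", starts[i] - 1L, min(starts[i] - 1L + widths[i], 60), vals[i],
          sep = "\t")))
  f <- tempfile(fileext = ".bedGraph")
  writeLines(lines, f)
  tr3 <- load_conservation(f, genome)
  oracle <- rep(NA_real_, 60)
  for (i in seq_len(n_rec)) {
    e <- min(starts[i] - 1L + widths[i], 60)
    if (e >= starts[i]) oracle[starts[i]:e] <- vals[i]
  }
  expect_equal(tr3$scores$s1, oracle)
})

test_that("out-of-range conservation scores are clamped with a warning", {
  expect_warning(tr <- conservation_track(list(s1 = c(0.5, 1.2, -0.1))),
                 "clamped")
  expect_equal(tr$scores$s1, c(0.5, 1, 0))
})

test_that("conservation round-trips through fixedStep wiggle", {
  scores <- list(s1 = c(NA, NA, 0.25, 0.5, NA, 0.75, 0.8, NA),
                 s2 = c(0.1, 0.2, NA))
  tr <- conservation_track(scores)
  f <- tempfile(fileext = ".wig")
  write_conservation(tr, f)
  genome <- make_genome(s1 = "ACGTACGT", s2 = "ACG")
  back <- load_conservation(f, genome)
  expect_equal(back$scores, scores)
})
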