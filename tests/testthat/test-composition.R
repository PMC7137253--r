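test_that("base composition pools regions and excludes N from the denominator", {
  genome <- make_genome(s1 = "GGCCATATNNNN")
  gc <- base_composition(GRanges("s1", IRanges(1, 4)), genome)
  expect_equal(gc$gc_fraction, 1.0)
  at <- base_composition(GRanges("s1", IRanges(5, 8)), genome)
  expect_equal(at$gc_fraction, 0.0)
  both <- base_composition(GRanges("s1", IRanges(c(1, 5), c(4, 12))), genome)
  expect_equal(both$total_bases, 8)  # the 4 Ns are excluded
  expect_equal(both$gc_fraction, 0.5)
  expect_equal(sum(both$base_fractions), 1)
  expect_error(base_composition(GRanges(), genome), "empty")
})

test_that("dinucleotide densities count overlapping offsets within regions", {
  genome <- make_genome(s1 = "CGCGCGCACA")
  cg_region <- GRanges("s1", IRanges(1, 6))  # "CGCGCG": CG at offsets 1,3,5
  expect_equal(dinucleotide_density(cg_region, genome, "CG"), 100 * 3 / 6)
  ca_region <- GRanges("s1", IRanges(7, 10))  # "CACA": CA at 1,3
  expect_equal(dinucleotide_density(ca_region, genome, "CA|TG"), 100 * 2 / 4)
  # dinucleotides spanning region boundaries are not counted
  split_regions <- GRanges("s1", IRanges(c(1, 4), c(3, 6)))
  whole <- GRanges("s1", IRanges(1, 6))
  expect_equal(dinucleotide_density(split_regions, genome, "CG") * 6 / 100, 2)
  expect_equal(dinucleotide_density(whole, genome, "CG") * 6 / 100, 3)
})

test_that("densities and O/E match a naive sliding-window oracle on random sequence", {
  genome <- random_genome(c(s1 = 1000), seed = 21)
  s <- as.character(genome[["s1"]])
  regions <- GRanges("s1", IRanges(c(1, 301, 650), c(250, 600, 1000)))
  seqs <- as.character(region_seqs(regions, genome))
  cg <- sum(vapply(seqs, oracle_kmer_count, integer(1), word = "CG"))
  catg <- sum(vapply(seqs, oracle_kmer_count, integer(1), word = "CA")) +
    sum(vapply(seqs, oracle_kmer_count, integer(1), word = "TG"))
  total <- sum(nchar(seqs))
  expect_equal(dinucleotide_density(regions, genome, "CG"), 100 * cg / total)
  expect_equal(dinucleotide_density(regions, genome, "CA|TG"),
               100 * catg / total)

  oe <- kmer_oe(regions, genome, k = 2)
  for (i in seq_len(nrow(oe))) {
    members <- strsplit(oe$members[i], "/")[[1]]
    o_count <- sum(vapply(members, function(m)
      sum(vapply(seqs, oracle_kmer_count, integer(1), word = m)), integer(1)))
    e_count <- sum(vapply(members, function(m)
      oracle_kmer_count(s, m), integer(1)))
    expect_equal(oe$observed[i], o_count / (total - length(seqs)))
    expect_equal(oe$expected[i], e_count / (nchar(s) - 1))
  }
})

test_that("k-mer class collapsing yields 10 dinucleotide and 32 trinucleotide classes", {
  expect_equal(nrow(kmer_classes(2)), 10)
  expect_equal(nrow(kmer_classes(3)), 32)
  genome <- random_genome(c(s1 = 500), seed = 3)
  expect_equal(nrow(kmer_oe(whole_genome_regions(genome), genome, 2)), 10)
  expect_equal(nrow(kmer_oe(whole_genome_regions(genome), genome, 3)), 32)
})

test_that("the whole genome as its own region set gives O/E exactly 1", {
  genome <- random_genome(c(s1 = 4000, s2 = 2500), seed = 13)
  for (k in c(2L, 3L)) {
    oe <- kmer_oe(whole_genome_regions(genome), genome, k)
    present <- !oe$undefined
    expect_true(all(oe$oe[present] == 1.0))
  }
})

test_that("regions covering a CG-rich genome half show CG class O/E above 1", {
  half_a <- paste(rep("CG", 250), collapse = "")
  half_b <- paste(rep(c("A", "T", "A", "A"), 125), collapse = "")
  genome <- make_genome(s1 = paste0(half_a, half_b))
  oe <- kmer_oe(GRanges("s1", IRanges(1, 500)), genome, 2)
  expect_gt(oe$oe[oe$representative == "CG"], 1)
})

test_that("GC, CpG and CA|TG metrics are strand symmetric", {
  genome <- random_genome(c(s1 = 2000), seed = 31)
  regions <- GRanges("s1", IRanges(c(11, 501, 1200), c(400, 900, 1900)))
  fwd <- region_seqs(regions, genome)
  rev <- reverseComplement(fwd)
  expect_equal(base_composition(fwd)$gc_fraction,
               base_composition(rev)$gc_fraction)
  expect_equal(dinucleotide_density(fwd, class = "CG"),
               dinucleotide_density(rev, class = "CG"))
  expect_equal(dinucleotide_density(fwd, class = "CA|TG"),
               dinucleotide_density(rev, class = "CA|TG"))
})

test_that("per-region values are average-consistent with the pooled profile", {
  genome <- random_genome(c(s1 = 3000), seed = 8)
  regions <- GRanges("s1", IRanges(c(1, 1001, 2001), width = 1000))
  per <- per_region_composition(regions, genome)
  pooled <- composition_profile(regions, genome)
  # equal-width regions: the pooled value is the exact mean for GC
  expect_equal(mean(per$gc_fraction), pooled$gc_fraction)
  w <- per$n_bases / sum(per$n_bases)
  expect_equal(sum(w * per$cpg_density), pooled$cpg_density)
  expect_equal(sum(w * per$catg_density), pooled$catg_density)
})

test_that("compare_sets separates a planted high-GC set from background", {
  set.seed(44)
  bg <- DNAStringSet(vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                 prob = c(.3, .2, .2, .3)), collapse = ""), character(1)))
  hi <- DNAStringSet(vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                 prob = c(.2, .3, .3, .2)), collapse = ""), character(1)))
  names(bg) <- paste0("b", 1:60); names(hi) <- paste0("h", 1:60)
  cmp <- compare_sets(list(background = per_region_composition(bg),
                           planted = per_region_composition(hi)))
  med <- cmp$summary[cmp$summary$metric == "gc_fraction", ]
  expect_gt(med$median[med$set == "planted"],
            med$median[med$set == "background"])
  # identical sets give identical medians
  cmp2 <- compare_sets(list(a = per_region_composition(bg),
                            b = per_region_composition(bg)))
  s2 <- cmp2$summary[cmp2$summary$metric == "cpg_density", ]
  expect_equal(s2$median[s2$set == "a"], s2$median[s2$set == "b"])
})

test_that("the mononucleotide background reproduces the CpG-island-style expectation", {
  genome <- random_genome(c(s1 = 5000), seed = 55)
  regions <- GRanges("s1", IRanges(1, 5000))
  oe <- kmer_oe(regions, genome, 2, background = "mononucleotide")
  fr <- base_composition(region_seqs(regions, genome))$base_fractions
  cg_row <- oe[oe$representative == "CG", ]
  expect_equal(cg_row$expected, unname(fr["C"] * fr["G"]))
  expect_equal(attr(oe, "background"), "mononucleotide")
})
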