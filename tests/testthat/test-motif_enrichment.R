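sharp_pwm <- function(word, id = "m", major = 0.85) {
  bases <- strsplit(word, "")[[1]]
  m <- matrix((1 - major) / 3 * 100, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- major * 100
  pwm(id, m)
}

uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("TRANSFAC files round-trip and preserve probabilities", {
  p1 <- sharp_pwm("TGACTCA", "motif_one")
  p2 <- pwm("motif_two", matrix(c(10, 0, 0, 2,
                                  0, 8, 2, 0,
                                  1, 1, 9, 1,
                                  3, 3, 3, 3), nrow = 4, byrow = TRUE))
  f <- tempfile(fileext = ".dat")
  write_transfac(list(p1, p2), f)
  back <- read_transfac(f)
  expect_setequal(names(back), c("motif_one", "motif_two"))
  expect_equal(back$motif_one$probs, p1$probs, tolerance = 1e-9)
  expect_equal(back$motif_two$probs, p2$probs, tolerance = 1e-9)
  # consensus is recoverable from the dominant rows
  cons <- paste(c("A", "C", "G", "T")[apply(back$motif_one$probs, 2, which.max)],
                collapse = "")
  expect_equal(cons, "TGACTCA")
})

test_that("malformed TRANSFAC rows fail naming the motif", {
  f <- tempfile(fileext = ".dat")
  writeLines(c("ID broken_motif", "P0  A  C  G  T", "01  1  2  x  4",
               "XX", "//"), f)
  expect_error(read_transfac(f), "broken_motif")
})

test_that("a uniform matrix has zero log-odds against a uniform background", {
  u <- pwm("uniform", matrix(25, nrow = 4, ncol = 6))
  lo <- pwm_logodds(u, uniform_bg)
  expect_true(all(abs(lo) < 1e-12))
})

test_that("the score threshold matches exhaustive enumeration of the window distribution", {
  set.seed(10)
  for (rep_i in 1:4) {
    L <- 5
    counts <- matrix(rexp(4 * L), nrow = 4) * 100
    p <- pwm("r", counts)
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    gran <- 0.01
    thr <- score_threshold(p, bg, p_site = 0.01, granularity = gran)
    # oracle: enumerate all 4^L words on the same score grid
    lo_grid <- round(pwm_logodds(p, bg) / gran)
    words <- expand.grid(rep(list(1:4), L))
    w_score <- rowSums(vapply(seq_len(L), function(j)
      lo_grid[cbind(words[[j]], j)], numeric(nrow(words))))
    w_prob <- apply(vapply(seq_len(L), function(j)
      c(0.3, 0.2, 0.2, 0.3)[words[[j]]], numeric(nrow(words))), 1, prod)
    achievable <- sort(unique(w_score))
    tails <- vapply(achievable, function(t) sum(w_prob[w_score >= t]),
                    numeric(1))
    want <- achievable[tails <= 0.01][1] * gran
    expect_equal(thr, want)
    # tail bound actually holds
    expect_lte(sum(w_prob[w_score * gran >= thr]), 0.01)
  }
})

test_that("scan scores equal a naive per-window loop on both strands", {
  genome <- random_genome(c(s1 = 10000), seed = 14)
  p <- sharp_pwm("TGACTCAT", major = 0.7)
  bg <- genome_background(genome)
  occ <- scan_genome(p, genome, p_site = 0.005)
  s <- as.character(genome[["s1"]])
  thr <- score_threshold(p, bg, p_site = 0.005)
  # naive loop on the same 0.01-bit grid the scanner selects on
  grid_oracle <- function(seq_char, probs) {
    lo <- round(log2(sweep(probs, 1, bg, "/")) / 0.01)
    chars <- strsplit(seq_char, "")[[1]]
    L <- ncol(probs)
    vapply(1:(nchar(seq_char) - L + 1), function(i)
      sum(vapply(1:L, function(j) lo[chars[i + j - 1], j], numeric(1))),
      numeric(1))
  }
  fwd <- grid_oracle(s, p$probs)
  # a minus-strand hit at i scores the reverse complement of the window
  # against the forward matrix
  L <- ncol(p$probs)
  lo <- round(log2(sweep(p$probs, 1, bg, "/")) / 0.01)
  chars <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev <- vapply(1:(nchar(s) - L + 1), function(i) {
    w <- rev(comp[chars[i:(i + L - 1)]])
    sum(vapply(1:L, function(j) lo[w[j], j], numeric(1)))
  }, numeric(1))
  thr_int <- round(thr / 0.01)
  want_pos <- sort(unique(c(which(fwd >= thr_int), which(rev >= thr_int))))
  expect_equal(sort(unique(start(occ))), want_pos)
  # scores agree with the oracle at reported positions
  for (i in seq_along(occ)) {
    pos <- start(occ)[i]
    want <- if (as.character(strand(occ))[i] == "+") fwd[pos] else rev[pos]
    expect_equal(occ$score[i], want * 0.01)
  }
})

test_that("windows containing N are skipped", {
  genome <- make_genome(s1 = paste0(strrep("A", 50), "TGACTCAT",
                                    strrep("N", 20), strrep("A", 50)))
  p <- sharp_pwm("TGACTCAT")
  occ <- scan_genome(p, genome, p_site = 1e-3,
                     background = uniform_bg)
  expect_true(all(end(occ) < 59 | start(occ) > 78))
  expect_equal(length(occ[start(occ) == 51]), 1L)
})

test_that("planted exact sites are recovered exactly at p_site 1e-4", {
  # the p-value bound caps the per-window false-hit probability near
  # p_site, so exact recovery needs windows * p_site << 1: a short random
  # background, and neutral flanks so planting cannot spawn extra
  # reverse-strand matches
  plant <- function(chars, word, sites) {
    wl <- nchar(word)
    for (st in sites) {
      chars[(st - 6):(st + wl + 5)] <- "A"
      chars[st:(st + wl - 1)] <- strsplit(word, "")[[1]]
    }
    chars
  }
  set.seed(26)
  chars <- plant(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                 "TGACTGCATT", c(201, 601, 1001))
  genome <- make_genome(s1 = paste(chars, collapse = ""))
  occ <- scan_genome(sharp_pwm("TGACTGCATT"), genome, p_site = 1e-4,
                     background = uniform_bg)
  expect_equal(sort(start(occ)), c(201, 601, 1001))

  # 6-mer needs a background under which the consensus window probability
  # is below the bound: GC-rich word against an AT-rich background
  skew_bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  set.seed(27)
  chars6 <- plant(sample(names(skew_bg), 1200, replace = TRUE, prob = skew_bg),
                  "GGCCGC", c(201, 601, 1001))
  genome6 <- make_genome(s1 = paste(chars6, collapse = ""))
  occ6 <- scan_genome(sharp_pwm("GGCCGC"), genome6, p_site = 1e-4,
                      background = skew_bg)
  expect_equal(sort(start(occ6)), c(201, 601, 1001))
})

test_that("palindromic hits are deduplicated to one occurrence", {
  word <- "TGATCA"  # reverse complement of itself
  genome <- make_genome(s1 = paste0(strrep("C", 40), word, strrep("C", 40),
                                    word, strrep("C", 40)))
  p <- pwm("pal", {
    m <- matrix(1, nrow = 4, ncol = 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(strsplit(word, "")[[1]], c("A", "C", "G", "T")), 1:6)] <- 97
    m
  })
  occ <- scan_genome(p, genome, p_site = 1e-3, background = uniform_bg)
  expect_equal(sum(start(occ) == 41), 1L)
  expect_equal(length(occ), 2L)
})

test_that("enrichment follows E = OCC_obs / (N * L_r / L_g) identities", {
  genome <- random_genome(c(s1 = 1000), seed = 2)
  # toy case: N = 50, L_r/L_g = 0.1, 20 overlapping occurrences -> E = 4
  inside <- GRanges("s1", IRanges(sample(1:91, 20, replace = TRUE), width = 10))
  outside <- GRanges("s1", IRanges(sample(201:900, 30, replace = TRUE),
                                   width = 10))
  occ <- c(inside, outside)
  occ$motif_id <- "m"
  occ$score <- 1
  region <- GRanges("s1", IRanges(1, 100))
  res <- motif_enrichment(occ, region, genome)
  expect_equal(res$occ_exp, 50 * 100 / 1000)
  expect_equal(res$occ_obs, 20L)
  expect_equal(res$enrichment, 4.0)
  # region set = whole genome -> E exactly 1
  res_all <- motif_enrichment(occ, whole_genome_regions(genome), genome)
  expect_equal(res_all$occ_obs, 50L)
  expect_equal(res_all$enrichment, 1.0)
  expect_error(motif_enrichment(occ, GRanges(), genome), "L_r")
})

test_that("occ_obs equals a brute-force overlap count and is monotone in regions", {
  set.seed(33)
  genome <- random_genome(c(s1 = 5000), seed = 3)
  occ <- GRanges("s1", IRanges(sample.int(4990, 200, replace = TRUE),
                               width = 8))
  occ$motif_id <- "m"; occ$score <- 0
  region_a <- GRanges("s1", IRanges(sample.int(4500, 10), width = 200))
  region_b <- c(region_a, GRanges("s1", IRanges(sample.int(4500, 10),
                                                width = 200)))
  res_a <- motif_enrichment(occ, region_a, genome)
  res_b <- motif_enrichment(occ, region_b, genome)
  brute <- sum(vapply(seq_along(occ), function(i)
    any(start(occ)[i] <= end(region_a) & end(occ)[i] >= start(region_a)),
    logical(1)))
  expect_equal(res_a$occ_obs, brute)
  expect_gte(res_b$occ_obs, res_a$occ_obs)
})

test_that("E is invariant under uniform scaling of genome, regions and occurrences", {
  set.seed(71)
  base_occ <- sample.int(990, 60)
  genome1 <- random_genome(c(s1 = 1000), seed = 4)
  genome2 <- random_genome(c(s1 = 1000, s2 = 1000), seed = 4)
  occ1 <- GRanges("s1", IRanges(base_occ, width = 6), motif_id = "m", score = 0)
  occ2 <- GRanges(rep(c("s1", "s2"), each = length(base_occ)),
                  IRanges(rep(base_occ, 2), width = 6),
                  motif_id = "m", score = 0)
  reg1 <- GRanges("s1", IRanges(101, 300))
  reg2 <- GRanges(c("s1", "s2"), IRanges(c(101, 101), c(300, 300)))
  e1 <- motif_enrichment(occ1, reg1, genome1)$enrichment
  e2 <- motif_enrichment(occ2, reg2, genome2)$enrichment
  expect_equal(e1, e2)
})

test_that("enrichment scatter is exact under identity and scaling", {
  res <- data.frame(motif_id = letters[1:5], enrichment = c(1, 2, 3, 4, 5))
  same <- enrichment_scatter(res, res)
  expect_equal(same$r, 1.0)
  doubled <- res; doubled$enrichment <- 2 * res$enrichment
  expect_equal(enrichment_scatter(res, doubled)$r, 1.0)
  expect_error(enrichment_scatter(res,
                                  data.frame(motif_id = "z", enrichment = 1)),
               "shared")
})

test_that("planted k-fold motif enrichment is recovered within 50 percent", {
  for (k in c(2, 4)) {
    b <- simulate_bundle(medium_bundle_config(seed = 300 + k, motif_fold = k,
                                              motif_site_rate = 2.5e-4))
    n_sites <- length(b$truth$motif_sites)
    expect_gte(n_sites, 200)
    occ <- scan_genome(b$pwms$planted, b$genome, p_site = 1e-4)
    sis <- unique_sisrnas(classify_peaks(b$peaks, b$genes,
                                         introns = b$introns))
    res <- motif_enrichment(occ, sis, b$genome)
    expect_gte(res$enrichment, 0.5 * k)
    expect_lte(res$enrichment, 1.5 * k)
  }
})
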