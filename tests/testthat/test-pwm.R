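test_that("a single-position motif has the closed-form score and p-value", {
  m <- motifModel("onlyA", matrix(c(1, 0, 0, 0), 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL)),
                  pseudocount = 0, pvalue_threshold = 0.3)
  dist <- pwmScoreDistribution(m)
  ## score at A is log2(1/0.25) = 2 bits with null probability 0.25
  top <- max(dist$support)
  expect_equal(top * tepbat:::PWM_BIN_BITS, 2)
  expect_equal(tepbat:::pwmPValue(dist, top), 0.25)
  hits <- scanPwm("TTATT", m, both_strands = FALSE)
  expect_equal(hits$start, 3L)
  expect_equal(hits$score, 2)
  expect_equal(hits$p_value, 0.25)
})

test_that("a length-4 exact-match motif has best-score p-value (1/4)^4", {
  cons <- "ACGT"
  mm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  mm[cbind(match(strsplit(cons, "")[[1]], rownames(mm)), 1:4)] <- 1
  m <- motifModel("exact4", mm, pseudocount = 0, pvalue_threshold = 1)
  dist <- pwmScoreDistribution(m)
  expect_equal(tepbat:::pwmPValue(dist, max(dist$support)), 0.25^4)
})

test_that("DP p-values equal brute-force enumeration for motifs of length <= 6", {
  set.seed(17)
  for (L in 2:6) {
    pwm <- randomPwm(L)
    bg <- as.numeric(stats::runif(4, 0.5, 1.5)); bg <- bg / sum(bg)
    m <- motifModel("rnd", pwm, background = bg, pseudocount = 0)
    dist <- pwmScoreDistribution(m)
    S <- tepbat:::pwmIntScores(m)
    ## enumerate all 4^L words
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    wscore <- rowSums(matrix(S[cbind(as.vector(words),
                                     rep(1:L, each = nrow(words)))],
                             nrow(words)))
    wprob <- apply(matrix(bg[as.vector(words)], nrow(words)), 1, prod)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
    for (thr in stats::quantile(wscore, c(0.05, 0.5, 0.9, 1))) {
      expect_equal(tepbat:::pwmPValue(dist, as.integer(thr)),
                   sum(wprob[wscore >= as.integer(thr)]), tolerance = 1e-9)
    }
  }
})

test_that("scanning reports both strands with correct coordinates and respects length limits", {
  m <- syntheticMotifs()$Maz_syn     # consensus GGGAGGGG
  seq <- paste0("TTTTT", "GGGAGGGG", "TTTTTTT", "CCCCTCCC", "TT")
  hits <- scanPwm(seq, m)
  expect_equal(nrow(hits), 2L)
  fwd <- hits[hits$strand == "+", ]; rev <- hits[hits$strand == "-", ]
  expect_equal(fwd$start, 6L); expect_equal(fwd$end, 13L)
  expect_equal(rev$start, 21L); expect_equal(rev$end, 28L)
  expect_equal(fwd$score, rev$score)
  ## motif longer than the sequence: empty result
  expect_equal(nrow(scanPwm("GGG", m)), 0L)
})

test_that("MEME round-trip preserves the motif models", {
  f <- tempfile(fileext = ".meme")
  writeMemeMotifs(syntheticMotifs(), f)
  back <- readMemeMotifs(f)
  expect_setequal(names(back), c("Maz_syn", "Ubp1_syn"))
  orig <- syntheticMotifs()
  expect_equal(motifMatrix(back$Maz_syn), motifMatrix(orig$Maz_syn),
               tolerance = 1e-5)
  ## the installed copy parses identically
  shipped <- readMemeMotifs(system.file("extdata", "synthetic_motifs.meme",
                                        package = "tepbat"))
  expect_equal(motifMatrix(shipped$Ubp1_syn), motifMatrix(orig$Ubp1_syn),
               tolerance = 1e-5)
})

test_that("clade-specific motif presence reaches the minimal possible p for its margins", {
  set.seed(23)
  rnd <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "T"), len, TRUE), collapse = ""), character(1))
  motif <- syntheticMotifs()$Maz_syn
  withm <- paste0(rnd(11, 40), "GGGAGGGG", rnd(11, 40))
  without <- paste0(rnd(34, 88))
  res <- cladeMotifEnrichment(list(hypo = withm, hyper = without),
                              list(motif), estimate_background = FALSE)
  expect_equal(res$present_hypo, 11L)
  expect_equal(res$present_hyper, 0L)
  expect_equal(res$p_value, 1 / choose(45, 11), tolerance = 1e-9)
  ## motif present everywhere: no association
  res2 <- cladeMotifEnrichment(list(hypo = withm[1:5], hyper = withm[6:11]),
                               list(motif), estimate_background = FALSE)
  expect_equal(res2$p_value, 1)
  expect_error(cladeMotifEnrichment(list(hypo = character(), hyper = "ACGT"),
                                    list(motif)), "empty")
})

test_that("CpG counting is position-based and clade CpG excess near motifs is detected", {
  d <- cpgDensityByClade(list(hypo = c(a = "CGCG"), hyper = c(b = "ATATAT")))
  expect_equal(d$per_sequence$cpg_total, c(2L, 0L))
  ## planted extra CpGs near motifs in the hypomethylated clade
  set.seed(29)
  rnd <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "T", "G"), len, TRUE), collapse = ""), character(1))
  motifs <- list(syntheticMotifs()$Maz_syn)
  hypo <- paste0(rnd(10, 30), "CGACGTCG", "GGGAGGGG", "CGTTCGAA", rnd(10, 30))
  hyper <- paste0(rnd(12, 30), "AAAAATTT", "GGGAGGGG", "ATTTATAA", rnd(12, 30))
  dd <- cpgDensityByClade(list(hypo = hypo, hyper = hyper), motifs, window = 10L)
  expect_lt(dd$p_near_motif, 0.01)
})
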