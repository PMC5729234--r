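test_that("a single unmutated solo copy is planted verbatim at its recorded locus", {
  cfg <- simConfig(seed = 3L, copy_plan = data.frame(
    subfamily = "IAPLTR1", n_solo = 1L, n_full = 0L, n_hypo = 0L,
    hypo_tissue = NA), mutation_rate = 0)
  sim <- buildGenome(cfg)
  cons <- as.character(sim$consensi[["IAPLTR1"]])
  ann <- sim$annotation
  expect_equal(length(ann), 1L)
  realized <- as.character(copySequences(sim$genome, ann))
  expect_identical(unname(realized), cons)
  ## the consensus occurs exactly once in the genome (either orientation)
  n_fwd <- sum(vapply(sim$genome, function(s)
    Biostrings::countPattern(cons, s), integer(1)))
  n_rev <- sum(vapply(sim$genome, function(s)
    Biostrings::countPattern(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cons))), s),
    integer(1)))
  expect_equal(n_fwd + n_rev, 1L)
})

test_that("a provirus yields paired 5'/3' LTR rows in strand order plus an internal row", {
  cfg <- simConfig(seed = 4L, copy_plan = data.frame(
    subfamily = "IAPLTR2a2", n_solo = 0L, n_full = 1L, n_hypo = 0L,
    hypo_tissue = NA))
  sim <- buildGenome(cfg)
  ann <- as.data.frame(sim$annotation)
  ltr <- ann[ann$class == "ltr", ]
  expect_equal(nrow(ltr), 2L)
  expect_equal(length(unique(ltr$element_id)), 1L)
  expect_setequal(ltr$feature, c("five_prime", "three_prime"))
  int <- ann[ann$class == "internal", ]
  expect_equal(int$element_id, ltr$element_id[1])
  ## genomic order depends on strand: + strand has 5' LTR leftmost
  left <- ltr$feature[which.min(ltr$start)]
  expect_identical(left, if (ltr$strand[1] == "+") "five_prime" else "three_prime")
  ## internal lies between the LTRs
  expect_true(int$start > min(ltr$end) && int$end < max(ltr$start))
})

test_that("the generator is deterministic: same seed, same genome, annotation and reads", {
  cfg <- smallConfig(seed = 9L)
  s1 <- buildGenome(cfg); s2 <- buildGenome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(as.data.frame(s1$annotation), as.data.frame(s2$annotation))
  t1 <- assignMethylome(s1, cfg); t2 <- assignMethylome(s2, cfg)
  expect_identical(t1, t2)
  r1 <- simulateTepbatReads(s1, t1, cfg)
  r2 <- simulateTepbatReads(s2, t2, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
})

test_that("hypomethylated copies stay below 0.2 and other tissues draw from the high distribution", {
  cfg <- smallConfig(seed = 21L)
  sim <- buildGenome(cfg)
  truth <- assignMethylome(sim, cfg)
  hypo <- truth$levels[truth$levels$clade == "hypo", ]
  expect_gt(nrow(hypo), 0L)
  expect_true(all(hypo$level <= 0.2))
  sites <- merge(truth$sites, truth$levels, by = c("copy_id", "tissue"))
  expect_true(all(sites$prob[sites$clade == "hypo"] <= 0.2))
  ## a copy hypomethylated in sperm only is hypermethylated in tail
  ann <- as.data.frame(sim$annotation)
  sperm_only <- ann$copy_id[!is.na(ann$hypo_tissues) & ann$hypo_tissues == "sperm"]
  expect_gt(length(sperm_only), 0L)
  tail_lev <- truth$levels[truth$levels$tissue == "tail" &
                           truth$levels$copy_id %in% sperm_only, ]
  expect_true(all(tail_lev$level > 0.5))
  expect_true(all(tail_lev$clade == "hyper"))
})

test_that("hypermethylated copy-level means match the configured distribution (Monte Carlo)", {
  cfg <- simConfig(seed = 77L, copy_plan = data.frame(
    subfamily = "IAPLTR1", n_solo = 100L, n_full = 50L, n_hypo = 0L,
    hypo_tissue = NA), tissues = "sperm", flank_length = 80L,
    fragment_range = c(60L, 80L), read_length = 50L)
  sim <- buildGenome(cfg)
  truth <- assignMethylome(sim, cfg)
  lev <- truth$levels$level   # 200 hyper draws
  expect_equal(length(lev), 200L)
  se <- stats::sd(lev) / sqrt(length(lev))
  expect_lt(abs(mean(lev) - 0.9), 3 * se)
})

test_that("fragments stay within the configured range and reads are 100 bp", {
  cfg <- smallConfig(seed = 12L)
  sim <- buildGenome(cfg)
  truth <- assignMethylome(sim, cfg)
  reads <- simulateTepbatReads(sim, truth, cfg)
  len <- reads$truth$frag_end - reads$truth$frag_start + 1L
  expect_true(all(len >= 350L & len <= 450L))
  expect_true(all(nchar(reads$reads$read1) == 100L))
  expect_true(all(nchar(reads$reads$read2) == 100L))
})

test_that("deterministic conversion limits: fully methylated keeps CpG cytosines, fully unmethylated leaves none", {
  cfg <- simConfig(seed = 6L, copy_plan = data.frame(
    subfamily = "IAPLTR2a2", n_solo = 2L, n_full = 0L, n_hypo = 0L,
    hypo_tissue = NA), tissues = "sperm", conversion_rate = 1,
    molecules_per_copy = 8L, flank_meth_level = 0)
  sim <- buildGenome(cfg)
  truth <- assignMethylome(sim, cfg)

  ## all CpG truth = 0: the converted strand carries no cytosine at all,
  ## so the genomic parts of both reads are C-free (read 1 is the reverse
  ## complement of the converted strand, hence G-free)
  t0 <- truth
  t0$sites$prob <- 0
  r0 <- simulateTepbatReads(sim, t0, cfg)
  expect_false(any(grepl("C", substr(r0$reads$read2, 31, 100))))
  expect_false(any(grepl("G", substr(r0$reads$read1, 24, 100))))

  ## all CpG truth = 1: every genomic CpG covered by a read keeps its C;
  ## checked through the caller: all calls are methylated
  t1 <- truth
  t1$sites$prob <- 1
  cfg1 <- cfg
  cfg1@flank_meth_level <- 1
  r1 <- simulateTepbatReads(sim, t1, cfg1)
  tr <- trimReadPairs(r1$reads)
  mp <- mapReadPairs(tr, buildReducedIndex(sim$genome),
                     fragment_range = cfg@fragment_range)
  calls <- callMethylation(mp$alignments, sim$genome)
  expect_gt(sum(calls$meth), 0L)
  expect_equal(sum(calls$unmeth), 0L)
})

test_that("every read pair's truth origin lies within its copy's amplicon span", {
  run <- cachedRun()
  tt <- run$reads$truth
  ann <- as.data.frame(run$sim$annotation)
  ann <- ann[match(tt$copy_id, ann$copy_id), ]
  frmax <- 450L
  ## the fragment contains the primer site, which is inside the copy, and
  ## extends at most one fragment length away from it
  expect_true(all(tt$frag_start <= ann$end & tt$frag_end >= ann$start))
  expect_true(all(tt$frag_start >= ann$start - frmax))
  expect_true(all(tt$frag_end <= ann$end + frmax))
})

test_that("per-CpG methylation calls converge to the truth level over molecules", {
  ## one copy, truth forced to 0.5, depth >= 400: the pooled estimate must
  ## fall inside the 3-sigma binomial interval [0.425, 0.575]
  cfg <- simConfig(seed = 31L, copy_plan = data.frame(
    subfamily = "IAPLTR1", n_solo = 1L, n_full = 0L, n_hypo = 0L,
    hypo_tissue = NA), tissues = "sperm", molecules_per_copy = 400L)
  sim <- buildGenome(cfg)
  truth <- assignMethylome(sim, cfg)
  truth$sites$prob <- 0.5
  reads <- simulateTepbatReads(sim, truth, cfg)
  mp <- mapReadPairs(trimReadPairs(reads$reads), buildReducedIndex(sim$genome),
                     fragment_range = cfg@fragment_range)
  calls <- callMethylation(mp$alignments, sim$genome)
  rec <- aggregateLtrMethylation(calls, sim$annotation, statistic = "pooled")
  expect_gte(rec$total_calls, 400L)
  expect_gt(rec$mean_level, 0.425)
  expect_lt(rec$mean_level, 0.575)
})
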