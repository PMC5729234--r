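mkAnnotation <- function(n = 1L, width = 100L) {
  GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = (seq_len(n) - 1L) * 1000L + 1L, width = width),
    strand = "+",
    copy_id = paste0("c", seq_len(n)), subfamily = "IAPLTR1",
    class = "ltr", feature = "solo")
}

mkReport <- function(pos, meth, unmeth, tissue = "sperm") {
  data.frame(tissue = tissue, chrom = "chr1", pos = pos,
             meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
}

test_that("per-copy aggregation: mean of site levels, pooled option and call totals", {
  ann <- mkAnnotation()
  ## two CpGs with calls (3,1) and (1,3): levels 0.75/0.25, mean 0.5, 8 calls
  r <- aggregateLtrMethylation(mkReport(c(10L, 20L), c(3L, 1L), c(1L, 3L)), ann)
  expect_equal(r$mean_level, 0.5)
  expect_equal(r$total_calls, 8L)
  expect_equal(r$n_cpg_covered, 2L)
  ## all methylated
  r2 <- aggregateLtrMethylation(mkReport(c(10L, 20L), c(5L, 7L), c(0L, 0L)), ann)
  expect_equal(r2$mean_level, 1.0)
  ## mean-of-sites vs pooled on constructed counts
  cases <- list(
    list(m = c(9L, 1L), u = c(1L, 9L), mean = 0.5, pooled = 0.5),
    list(m = c(9L, 0L), u = c(1L, 10L), mean = 0.45, pooled = 0.45),
    list(m = c(10L, 81L), u = c(0L, 9L), mean = 0.95, pooled = 0.91))
  for (cs in cases) {
    rep_ <- mkReport(c(10L, 20L), cs$m, cs$u)
    expect_equal(aggregateLtrMethylation(rep_, ann)$mean_level, cs$mean)
    expect_equal(aggregateLtrMethylation(rep_, ann, statistic = "pooled")$mean_level,
                 cs$pooled)
  }
  ## a copy with no covered site: undefined mean, filter fails
  r3 <- aggregateLtrMethylation(mkReport(5000L, 3L, 1L), ann)
  expect_true(is.na(r3$mean_level))
  expect_false(r3$pass_filter)
})

test_that("the 20-call filter excludes 19 calls and keeps 20", {
  ann <- mkAnnotation()
  rec19 <- aggregateLtrMethylation(mkReport(c(10L, 20L), c(9L, 9L), c(0L, 1L)), ann)
  rec20 <- aggregateLtrMethylation(mkReport(c(10L, 20L), c(10L, 9L), c(0L, 1L)), ann)
  expect_equal(rec19$total_calls, 19L)
  expect_equal(rec20$total_calls, 20L)
  expect_equal(nrow(filterLtrs(rec19)), 0L)
  expect_equal(attr(filterLtrs(rec19), "n_excluded"), 1L)
  expect_equal(nrow(filterLtrs(rec20)), 1L)
  empty <- filterLtrs(rec19[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_excluded"), 0L)
  expect_error(filterLtrs(rec20, min_calls = -1L), "non-negative")
})

test_that("methylation bins use the closed boundaries low <= 0.2 < medium <= 0.8 < high", {
  expect_identical(binMethylation(0.2), "low")
  expect_identical(binMethylation(0.81), "high")
  expect_identical(binMethylation(0.5), "medium")
  expect_identical(binMethylation(0.8), "medium")
  expect_identical(binMethylation(c(0, 1)), c("low", "high"))
  expect_error(binMethylation(1.2), "outside")
  expect_error(binMethylation(-0.1), "outside")
})

test_that("bin partition and filter monotonicity hold over random records", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    rec <- data.frame(copy_id = paste0("c", 1:n), tissue = "sperm",
                      n_cpg_covered = sample(1:20, n, TRUE),
                      total_calls = sample(0:200, n, TRUE),
                      mean_level = stats::runif(n))
    f1 <- filterLtrs(rec, min_calls = 20L)
    expect_true(all(table(f1$bin) >= 0))
    expect_equal(sum(f1$bin %in% c("low", "medium", "high")), nrow(f1))
    f2 <- filterLtrs(rec, min_calls = 50L)
    expect_true(all(f2$copy_id %in% f1$copy_id))
  }
})

test_that("the joint table intersects tissues and counts the both-hypomethylated overlap", {
  ann <- mkAnnotation(3L)
  ## c1 passes in both (low/low), c2 passes in sperm only, c3 high in both
  rep_sperm <- rbind(
    mkReport(c(10L, 20L), c(1L, 1L), c(14L, 14L)),            # c1: 0.066
    mkReport(c(1010L, 1020L), c(20L, 20L), c(0L, 0L)),        # c2
    mkReport(c(2010L, 2020L), c(20L, 20L), c(1L, 1L)))        # c3: 0.952
  rep_tail <- rbind(
    mkReport(c(10L, 20L), c(2L, 0L), c(18L, 20L), "tail"),    # c1: 0.05
    mkReport(c(1010L, 1020L), c(4L, 4L), c(1L, 1L), "tail"),  # c2: 10 calls
    mkReport(c(2010L, 2020L), c(30L, 28L), c(0L, 2L), "tail"))# c3
  rec <- rbind(aggregateLtrMethylation(rep_sperm, ann),
               aggregateLtrMethylation(rep_tail, ann))
  joint <- jointTissueTable(rec)
  expect_setequal(joint$copy_id, c("c1", "c3"))
  both_low <- sum(joint$bin_sperm == "low" & joint$bin_tail == "low")
  expect_equal(both_low, 1L)
  sc <- attr(joint, "subfamily_counts")
  expect_equal(sc$analyzed, 2L)
  expect_equal(sc$genomic, 3L)
  expect_error(jointTissueTable(rec, tissues = c("sperm", "liver")), "absent")
  ## identical inputs for both tissues put every copy on the diagonal
  rec2 <- rbind(aggregateLtrMethylation(rep_sperm, ann),
                transform(aggregateLtrMethylation(rep_sperm, ann), tissue = "tail"))
  j2 <- jointTissueTable(rec2)
  expect_equal(j2$level_sperm, j2$level_tail)
})

test_that("recovered per-copy levels sit within binomial 3-sigma of truth for >= 99% of deep copies", {
  run <- cachedRun()
  ## the binomial bound describes the pooled-calls estimator: per-CpG truth
  ## equals the copy mean, so pooled calls are iid Bernoulli(truth)
  rec <- aggregateLtrMethylation(run$calls, run$sim$annotation,
                                 statistic = "pooled")
  rec <- rec[rec$total_calls >= 100, ]
  m <- merge(rec, run$truth$levels, by = c("copy_id", "tissue"))
  expect_gt(nrow(m), 20L)
  sigma <- sqrt(pmax(m$level * (1 - m$level), 1e-6) / m$total_calls)
  ok <- abs(m$mean_level - m$level) <= pmax(3 * sigma, 0.02)
  expect_gte(mean(ok), 0.99)
})
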