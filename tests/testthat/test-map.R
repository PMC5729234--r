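test_that("alphabet reductions follow the bisulfite definition", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  idx <- buildReducedIndex(g)
  expect_identical(as.character(idx@ct)[["chr1"]], "ATGT")
  expect_identical(as.character(idx@ga)[["chr1"]], "ACAT")
  expect_error(buildReducedIndex(Biostrings::DNAStringSet()), "empty")
})

test_that("a query equal to a unique reduced substring has exactly one hit", {
  set.seed(100)
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")))
  idx <- buildReducedIndex(g)
  q <- chartr("C", "T", substr(as.character(g), 1001, 1070))
  hits <- tepbat:::reducedHits(q, idx, max_mismatch = 0L)
  expect_equal(sum(hits$context == "CT" & hits$mm == 0), 1L)
  expect_equal(hits$start[hits$context == "CT"][1], 1001L)
})

test_that("seeded index lookup agrees exactly with a brute-force scan on a 50-kb genome", {
  set.seed(2024)
  g <- Biostrings::DNAStringSet(c(
    chrA = paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  ## plant one exact repeat so some queries hit twice
  gA <- as.character(g[["chrA"]])
  substr(gA, 25001, 25080) <- substr(gA, 5001, 5080)
  g <- Biostrings::DNAStringSet(c(chrA = gA, chrB = as.character(g[["chrB"]])))
  idx <- buildReducedIndex(g)
  gchars <- strsplit(as.character(g), "")

  set.seed(7)
  n_checked <- 0L
  for (q in 1:100) {
    ch <- sample(names(g), 1)
    w <- sample(60:80, 1)
    st <- sample(length(gchars[[ch]]) - w, 1)
    raw <- paste(gchars[[ch]][st:(st + w - 1L)], collapse = "")
    ## emulate a bisulfite read: reduce, optionally reverse-complement,
    ## and inject up to 3 substitutions
    read <- if (stats::runif(1) < 0.5) chartr("C", "T", raw)
            else tepbat:::revComp(chartr("G", "A", raw))
    v <- strsplit(read, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      pos <- sample(w, nmut)
      v[pos] <- vapply(pos, function(p)
        sample(setdiff(c("A", "C", "G", "T"), v[p]), 1), character(1))
    }
    read <- paste(v, collapse = "")
    fast <- tepbat:::batchAnchorHits(read, idx, max_mismatch = 3L)[[1]]
    slow <- bruteHits(read, g, max_mismatch = 3L)
    if (is.null(fast)) {
      expect_null(slow)
    } else {
      fast <- fast[order(fast$chrom, fast$start, fast$context), ]
      expect_equal(fast[, c("chrom", "start", "context", "mm")],
                   slow[, c("chrom", "start", "context", "mm")],
                   ignore_attr = TRUE)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 100L)
})

test_that("an anchor planted identically at two loci is discarded as multi-hit", {
  cfg <- simConfig(seed = 8L, copy_plan = data.frame(
    subfamily = "IAPLTR1", n_solo = 2L, n_full = 0L, n_hypo = 0L,
    hypo_tissue = NA), tissues = "sperm", molecules_per_copy = 4L,
    conversion_rate = 1)
  sim <- buildGenome(cfg)
  ## duplicate the first copy's locus (copy + upstream flank) elsewhere so
  ## its anchors become ambiguous
  ann <- as.data.frame(sim$annotation)
  ann$seqnames <- as.character(ann$seqnames)
  lo <- max(1L, ann$start[1] - 600L); hi <- min(ann$end[1] + 600L,
    length(sim$genome[[ann$seqnames[1]]]))
  dup <- as.character(Biostrings::subseq(sim$genome[[ann$seqnames[1]]], lo, hi))
  sim$genome <- c(sim$genome, Biostrings::DNAStringSet(c(chrDup = dup)))
  truth <- assignMethylome(sim$annotation, cfg, genome = sim$genome)
  reads <- simulateTepbatReads(sim, truth, cfg)
  mp <- mapReadPairs(trimReadPairs(reads$reads), buildReducedIndex(sim$genome),
                     fragment_range = cfg@fragment_range)
  tt <- reads$truth
  dup_reads <- tt$read_id[tt$copy_id == ann$copy_id[1]]
  other_reads <- tt$read_id[tt$copy_id != ann$copy_id[1]]
  expect_true(all(dup_reads %in%
    mp$discards$read_id[mp$discards$reason == "multi_hit"]))
  expect_true(all(other_reads %in% mp$alignments$read_id))
})

test_that("placements match the simulated truth for >= 99% of non-discarded pairs", {
  run <- cachedRun()
  a <- run$mapped$alignments[run$mapped$alignments$which == "anchor", ]
  tt <- run$reads$truth[match(a$read_id, run$reads$truth$read_id), ]
  ok <- a$chrom == tt$chrom & a$start == tt$anchor_start & a$end == tt$anchor_end
  expect_gte(mean(ok), 0.99)
})

test_that("discard accounting is exact: pairs in = unique + discarded by reason", {
  run <- cachedRun()
  cnt <- run$mapped$counts
  expect_equal(unname(cnt["pairs_in"]),
               unname(cnt["pairs_unique"] + cnt["pairs_discarded"]))
  reasons <- cnt[grep("^discard_", names(cnt))]
  expect_equal(unname(cnt["pairs_discarded"]), sum(reasons))
  ## no pair is both aligned and discarded
  expect_length(intersect(run$mapped$alignments$read_id,
                          run$mapped$discards$read_id), 0L)
})

test_that("methylation calls count informative bases and collapse dyads to the + strand C", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTTTACGTTTTT"))
  ## CpG dyad: C at 6, G at 7 (+ strand coordinates)
  aln <- data.frame(read_id = c("a", "b", "c"), tissue = "t",
                    chrom = "chr1", start = c(3L, 3L, 4L), end = c(8L, 8L, 9L),
                    context = c("CT", "CT", "GA"),
                    projected = c("TTACGT",   # C retained: methylated
                                  "TTATGT",   # C converted: unmethylated
                                  "TACATT"),  # bottom strand: dyad G reads A
                    which = "anchor", stringsAsFactors = FALSE)
  calls <- callMethylation(aln, genome)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 6L)           # collapsed to the + strand C
  expect_equal(calls$meth, 1L)
  expect_equal(calls$unmeth, 2L)        # one T call + one A call (projected G->A)
  expect_error(callMethylation(transform(aln, end = 99L), genome), "contig")
})

test_that("per-site call conservation holds on a simulated run", {
  run <- cachedRun()
  calls <- run$calls
  ## every call is backed by an informative aligned base: depth at a site
  ## never exceeds the number of reads overlapping it
  aln <- run$mapped$alignments
  set.seed(1)
  for (i in sample(nrow(calls), 25)) {
    cover <- sum(aln$tissue == calls$tissue[i] & aln$chrom == calls$chrom[i] &
                 aln$start <= calls$pos[i] + 1L & aln$end >= calls$pos[i])
    expect_lte(calls$meth[i] + calls$unmeth[i], cover)
  }
})
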