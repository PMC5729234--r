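test_that("p-distances use pairwise gap deletion", {
  a <- alignmentFromSequences(c(x = "ACGT", y = "ACGA"))
  expect_equal(pairwiseDistances(a)["x", "y"], 0.25)
  b <- alignmentFromSequences(c(x = "ACGT", y = "ACGT"))
  expect_equal(pairwiseDistances(b)["x", "y"], 0)
  cc <- alignmentFromSequences(c(x = "AC-T", y = "ACGT"))
  expect_equal(pairwiseDistances(cc)["x", "y"], 0)   # 0 mismatches / 3 columns
  d <- alignmentFromSequences(c(x = "A---", y = "-CGT"))
  expect_error(pairwiseDistances(d), "comparable")
  expect_error(alignmentFromSequences(c(x = "ACGT", y = "ACG")), "unequal")
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c")))
  tr <- neighborJoining(D)
  expect_s3_class(tr, "phylo")
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
  expect_error(neighborJoining(matrix(c(0, 1, 1, 0), 2,
                                      dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 0.9
  expect_error(neighborJoining(Dbad), "symmetric")
})

test_that("identical taxa become siblings on zero-length pendant edges", {
  D <- matrix(c(0, 0, 0.4, 0.5,
                0, 0, 0.4, 0.5,
                0.4, 0.4, 0, 0.3,
                0.5, 0.5, 0.3, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighborJoining(D)
  ## a and b form a cherry: the single internal split is {a,b} | {c,d}
  sp <- tepbat:::treeSplits(tr)
  expect_equal(length(sp$sides), 1L)
  expect_true(setequal(sp$sides[[1]], c("a", "b")) ||
              setequal(sp$sides[[1]], c("c", "d")))
  bl <- stats::setNames(tr$edge.length, ifelse(tr$edge[, 2] <= 4,
                                               tr$tip.label[tr$edge[, 2]], ""))
  expect_equal(unname(bl["a"]), 0)
  expect_equal(unname(bl["b"]), 0)
})

test_that("NJ recovers the exact topology of additive matrices (n <= 12), matching ape", {
  for (seed in 1:8) {
    ntaxa <- sample(5:12, 1)
    ra <- randomAdditive(ntaxa, seed)
    tr <- neighborJoining(ra$D)
    ## path-length additivity oracle: the NJ tree must reproduce the input
    ## distances exactly
    got <- cophenetic(tr)[rownames(ra$D), colnames(ra$D)]
    expect_equal(got, ra$D, tolerance = 1e-6)
    ## cross-check topology against the independent ape implementation
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ape::nj(ra$D)))), 0)
  }
})

test_that("bootstrap strongly supports a planted two-clade split and is seed-reproducible", {
  set.seed(33)
  base <- sample(c("A", "C", "G", "T"), 120, TRUE)
  mk <- function(diag_cols, diag_base, label, n) {
    out <- list()
    for (i in seq_len(n)) {
      v <- base
      v[diag_cols] <- diag_base
      mut <- sample(120, 3)
      v[mut] <- vapply(mut, function(p)
        sample(setdiff(c("A", "C", "G", "T"), v[p]), 1), character(1))
      out[[sprintf("%s%02d", label, i)]] <- paste(v, collapse = "")
    }
    unlist(out)
  }
  seqs <- c(mk(1:12, "A", "u", 8), mk(1:12, "C", "m", 10))
  aln <- alignmentFromSequences(seqs)
  st <- bootstrapSupport(aln, replicates = 200L, seed = 7L)
  expect_true(all(st$support >= 0 & st$support <= 200L))
  sig <- paste(sort(grep("^u", rownames(aln), value = TRUE)), collapse = "|")
  alt <- paste(sort(grep("^m", rownames(aln), value = TRUE)), collapse = "|")
  sep_support <- max(st$support[names(st$support) %in% c(sig, alt)], 0)
  expect_gte(sep_support, 0.95 * 200)
  st2 <- bootstrapSupport(aln, replicates = 200L, seed = 7L)
  expect_identical(st$support, st2$support)
})

test_that("the hypomethylated clade is the supported side with the most hypomethylated leaves", {
  set.seed(44)
  base <- sample(c("A", "C", "G", "T"), 150, TRUE)
  mk <- function(cols, b, label, n) {
    out <- character(n)
    for (i in seq_len(n)) {
      v <- base; v[cols] <- b
      mut <- sample(150, 2)
      v[mut] <- vapply(mut, function(p)
        sample(setdiff(c("A", "C", "G", "T"), v[p]), 1), character(1))
      out[i] <- paste(v, collapse = "")
    }
    stats::setNames(out, sprintf("%s%02d", label, seq_len(n)))
  }
  ## study-scale composition: 11 hypomethylated + 34 hypermethylated, the
  ## hypomethylated sharing a diagnostic block
  seqs <- c(mk(1:10, "G", "u", 11), mk(1:10, "T", "m", 34))
  aln <- alignmentFromSequences(seqs)
  st <- bootstrapSupport(aln, replicates = 100L, seed = 3L)
  status <- stats::setNames(ifelse(grepl("^u", rownames(aln)), "hypo", "hyper"),
                            rownames(aln))
  clade <- findHypomethylatedClade(st, status, min_support = 0.8)
  expect_false(clade$fallback)
  expect_setequal(clade$members, names(status)[status == "hypo"])
  expect_equal(clade$fraction, 1)
  expect_equal(clade$n_hypo, 11L)
  ## an unreachable support threshold falls back to the whole tree
  expect_warning(fb <- findHypomethylatedClade(st, status, min_support = 1.01),
                 "support")
  expect_true(fb$fallback)
  expect_setequal(fb$members, rownames(aln))
})
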