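## shared fixtures, built in code at test time

## a small copy plan for quick simulations
smallPlan <- function() {
  data.frame(subfamily = c("IAPLTR1", "IAPLTR2a2"),
             n_solo = c(3L, 6L), n_full = c(1L, 1L),
             n_hypo = c(0L, 3L), hypo_tissue = c(NA, "sperm"),
             stringsAsFactors = FALSE)
}

smallConfig <- function(seed = 11L, ...) {
  simConfig(seed = seed, copy_plan = smallPlan(), n_hypo_both = 1L,
            molecules_per_copy = 10L, ...)
}

## one moderate pipeline run, shared by the pipeline and acceptance tests
## (memoised; built on first use)
.fixture_env <- new.env(parent = emptyenv())

cachedRun <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  cfg <- simConfig(seed = 42L, copy_plan = data.frame(
    subfamily = c("IAPLTR1", "IAPLTR2", "IAPLTR2a2"),
    n_solo = c(6L, 12L, 16L), n_full = c(3L, 2L, 3L),
    n_hypo = c(0L, 5L, 7L), hypo_tissue = c(NA, "tail", "sperm"),
    stringsAsFactors = FALSE),
    n_hypo_both = 1L, molecules_per_copy = 36L)
  .fixture_env$run <- suppressWarnings(
    runPipeline(cfg, outdir = NULL, bootstrap_replicates = 200L,
                verbose = FALSE))
  .fixture_env$run
}

## brute-force mismatch-tolerant search over all four bisulfite-reduction
## combinations: the independent oracle for the mapper
bruteHits <- function(seq, genome, max_mismatch = 3L) {
  combos <- list(
    list(p = chartr("C", "T", seq), red = "ct", context = "CT"),
    list(p = chartr("C", "T", tepbat:::revComp(seq)), red = "ct", context = "CT"),
    list(p = chartr("G", "A", tepbat:::revComp(seq)), red = "ga", context = "GA"),
    list(p = chartr("G", "A", seq), red = "ga", context = "GA"))
  out <- list()
  for (ch in names(genome)) {
    g <- as.character(genome[[ch]])
    imgs <- list(ct = strsplit(chartr("C", "T", g), "")[[1]],
                 ga = strsplit(chartr("G", "A", g), "")[[1]])
    for (k in seq_along(combos)) {
      pv <- strsplit(combos[[k]]$p, "")[[1]]
      img <- imgs[[combos[[k]]$red]]
      w <- length(pv); n <- length(img)
      if (n < w) next
      no <- n - w + 1L
      mm <- integer(no)
      for (i in seq_len(w)) mm <- mm + (img[seq_len(no) + i - 1L] != pv[i])
      hit <- which(mm <= max_mismatch)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = hit, context = combos[[k]]$context,
          mm = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  h <- do.call(rbind, out)
  h <- h[!duplicated(h[, c("chrom", "start", "context")]), , drop = FALSE]
  h[order(h$chrom, h$start, h$context), , drop = FALSE]
}

## brute-force two-sided Fisher p (minimum-likelihood method) for a 2x2
## table by enumerating the hypergeometric tail terms
bruteFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## random PWM of a given length (probabilities, columns sum to 1)
randomPwm <- function(L) {
  m <- matrix(stats::runif(4 * L, 0.02, 1), 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

## random additive distance matrix from a random binary tree; returns the
## matrix and the generating tree (ape phylo)
randomAdditive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE, br = function(n) stats::runif(n, 0.05, 1))
  D <- cophenetic(tr)
  labs <- sort(rownames(D))
  list(D = D[labs, labs], tree = tr)
}
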