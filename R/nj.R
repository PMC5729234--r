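#' Build an alignment matrix from equal-length sequences
#'
#' Copies of one subfamily are simulated with substitutions only, so their
#' realized sequences are naturally aligned; real data should be supplied
#' pre-aligned (gaps as "-").
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @return Character matrix (sequences x columns) over A,C,G,T,-.
#' @export
alignmentFromSequences <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths; supply a pre-computed alignment")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  bad <- !m %in% c("A", "C", "G", "T", "-", "N")
  if (any(bad)) stop("alignment contains characters outside {A,C,G,T,-,N}")
  m
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' d(i,j) = mismatches / compared columns, over the columns where both
#' rows are non-gap (and non-N).
#'
#' @param alignment Character matrix from [alignmentFromSequences()].
#' @return Symmetric numeric matrix, zero diagonal.
#' @examples
#' a <- alignmentFromSequences(c(x = "ACGT", y = "ACGA"))
#' pairwiseDistances(a)["x", "y"]  # 0.25
#' @export
pairwiseDistances <- function(alignment) {
  n <- nrow(alignment)
  ok <- alignment %in% c("A", "C", "G", "T")
  dim(ok) <- dim(alignment)
  D <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("no comparable columns between ", rownames(alignment)[i], " and ",
           rownames(alignment)[j])
    D[i, j] <- D[j, i] <- sum(alignment[i, comp] != alignment[j, comp]) / nc
  }
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Agglomerates by the Q-criterion with the standard branch-length
#' formulas; negative branch lengths are clamped to zero; ties on Q are
#' broken deterministically by the smallest (row, column) index pair.
#'
#' @param D Symmetric distance matrix with labelled dimnames, >= 3 taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighborJoining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  ## each active node is a newick subtree string
  sub <- labels
  D <- unname(D)
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    new_sub <- paste0("(", sub[i], ":", fmt(vi), ",", sub[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    D <- D2
  }
  ## closed-form three-point join
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(v1), ",", sub[2], ":", fmt(v2), ",",
                sub[3], ":", fmt(v3), ");")
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Canonical split signatures (the side not containing the first tip
#' label, sorted and joined) for every internal edge.
#'
#' @param tree A `phylo`.
#' @return Named integer-free list: `signature` character vector and
#'   `sides` list of leaf-label vectors (canonical side of each split).
#' @keywords internal
treeSplits <- function(tree) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(idx) tips[idx])
  ## drop the root clade (all tips); canonicalise to the side without tips[1]
  keep <- vapply(sides, function(s)
    length(s) >= 2L && length(s) <= length(tips) - 2L, logical(1))
  sides <- sides[keep]
  sides <- lapply(sides, function(s)
    if (tips[1] %in% s) setdiff(tips, s) else s)
  keep2 <- vapply(sides, function(s)
    length(s) >= 2L && length(s) <= length(tips) - 2L, logical(1))
  sides <- sides[keep2]
  sig <- vapply(sides, function(s) paste(sort(s), collapse = "|"), character(1))
  dup <- duplicated(sig)
  list(signature = sig[!dup], sides = sides[!dup])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/NJ tree per replicate, and counts how often each internal
#' bipartition of the original tree is recovered.
#'
#' @param alignment Character matrix from [alignmentFromSequences()].
#' @param replicates Number of bootstrap replicates (1000 in the standard
#'   workflow).
#' @param seed Integer seed; identical seeds give identical supports.
#' @return List of class `supportedTree`: `tree` (phylo, with
#'   `node.label`-free structure), `splits` (from [treeSplits()]),
#'   `support` (integer counts in [0, replicates]), `replicates`.
#' @export
bootstrapSupport <- function(alignment, replicates = 1000L, seed = 1L) {
  if (ncol(alignment) < 2L) stop("alignment needs >= 2 columns")
  tree <- neighborJoining(pairwiseDistances(alignment))
  sp <- treeSplits(tree)
  support <- stats::setNames(integer(length(sp$signature)), sp$signature)
  set.seed(as.integer(seed))
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(alignment), replace = TRUE)
    Db <- tryCatch(pairwiseDistances(alignment[, cols, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Db)) next
    spb <- treeSplits(neighborJoining(Db))
    hit <- sp$signature %in% spb$signature
    support[hit] <- support[hit] + 1L
  }
  out <- list(tree = tree, splits = sp, support = support,
              replicates = as.integer(replicates))
  class(out) <- c("supportedTree", "list")
  out
}

#' @export
print.supportedTree <- function(x, ...) {
  cat("supportedTree:", length(x$tree$tip.label), "leaves,",
      length(x$support), "internal splits,", x$replicates,
      "bootstrap replicates\n")
  invisible(x)
}

#' Write a supported tree as newick with support labels
#'
#' Supports are attached as internal node labels (counts out of the
#' replicate number).
#' @param st A `supportedTree`.
#' @param file Path.
#' @export
writeSupportedTree <- function(st, file) {
  tree <- st$tree
  ## attach support to matching internal nodes
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  labs <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    s <- tips[pp[[k]]]
    s <- if (tips[1] %in% s) setdiff(tips, s) else s
    sig <- paste(sort(s), collapse = "|")
    if (sig %in% names(st$support)) labs[k] <- as.character(st$support[[sig]])
  }
  tree$node.label <- labs
  ape::write.tree(tree, file)
  invisible(file)
}

#' Locate the hypomethylated clade
#'
#' Over internal bipartitions with bootstrap support at least
#' `min_support` (a fraction of replicates), picks the side with the most
#' hypomethylated leaves; ties are broken by higher hypomethylated
#' fraction, then by smaller clade.  With no supported edge, the whole
#' leaf set is returned with a warning.
#'
#' @param st A `supportedTree` from [bootstrapSupport()].
#' @param status Named character vector, "hypo"/"hyper" per leaf label.
#' @param min_support Fraction of replicates (default 0.8).
#' @return List: `members`, `n_hypo`, `fraction` (hypo fraction within the
#'   clade), `support` (replicate count of the chosen edge, NA for the
#'   fallback), `fallback`.
#' @export
findHypomethylatedClade <- function(st, status, min_support = 0.8) {
  tips <- st$tree$tip.label
  if (!all(tips %in% names(status))) stop("every leaf needs a hypo/hyper status")
  status <- status[tips]
  thr <- min_support * st$replicates
  cand <- list()
  for (k in seq_along(st$splits$sides)) {
    if (st$support[[k]] < thr) next
    side <- st$splits$sides[[k]]
    for (s in list(side, setdiff(tips, side))) {
      cand[[length(cand) + 1L]] <- list(
        members = s, n_hypo = sum(status[s] == "hypo"),
        fraction = mean(status[s] == "hypo"),
        support = st$support[[k]])
    }
  }
  if (!length(cand)) {
    warning("no internal edge reaches the support threshold; returning all leaves")
    return(list(members = tips, n_hypo = sum(status == "hypo"),
                fraction = mean(status == "hypo"), support = NA_integer_,
                fallback = TRUE))
  }
  ord <- order(-vapply(cand, `[[`, numeric(1), "n_hypo"),
               -vapply(cand, `[[`, numeric(1), "fraction"),
               vapply(cand, function(x) length(x$members), numeric(1)))
  best <- cand[[ord[1]]]
  c(best, list(fallback = FALSE))
}

#' Extract planted copy sequences in element orientation
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param annotation GRanges with `copy_id`.
#' @param ids Copy ids to extract (default all).
#' @return [Biostrings::DNAStringSet] named by copy_id; minus-strand
#'   copies are reverse-complemented into element orientation.
#' @export
copySequences <- function(genome, annotation, ids = NULL) {
  mc <- S4Vectors::mcols(annotation)
  if (!is.null(ids)) annotation <- annotation[mc$copy_id %in% ids]
  mc <- S4Vectors::mcols(annotation)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(annotation), function(i) {
    s <- Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(annotation))[i]]],
      GenomicRanges::start(annotation)[i], GenomicRanges::end(annotation)[i])
    if (as.character(GenomicRanges::strand(annotation))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(seqs) <- mc$copy_id
  if (!is.null(ids)) seqs <- seqs[ids]
  seqs
}
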