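#' Build the bisulfite-reduced genome index
#'
#' Computes the C->T and G->A reduced images of the genome.  Fully
#' converted fragments of the top strand match the C->T image; fragments
#' deriving from the bottom strand, projected onto top-strand coordinates,
#' match the G->A image.  Reads are looked up in both images in both
#' orientations (four combinations), mirroring the four alignment
#' strategies of standard bisulfite mappers.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @return A \linkS4class{ReducedIndex}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' idx <- buildReducedIndex(g)
#' as.character(idx@ct)  # "ATGT"
#' as.character(idx@ga)  # "ACAT"
#' @export
buildReducedIndex <- function(genome) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L || sum(S4Vectors::width(genome)) == 0L)
    stop("empty genome")
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  ct <- reduceCT(genome); ga <- reduceGA(genome)
  ## joined images with 100-N spacers: exact seeds never cross a spacer, so
  ## one search covers all contigs; placements overrunning a contig are
  ## filtered on conversion back to contig coordinates
  spacer <- strrep("N", 100L)
  w <- S4Vectors::width(genome)
  cat_offset <- cumsum(c(1L, utils::head(w + 100L, -1L)))
  new("ReducedIndex", genome = genome, ct = ct, ga = ga,
      ct_cat = Biostrings::DNAString(paste(as.character(ct), collapse = spacer)),
      ga_cat = Biostrings::DNAString(paste(as.character(ga), collapse = spacer)),
      cat_offset = as.integer(cat_offset))
}

SEED_LEN <- 16L

## the four reduction/orientation combinations of a read.
## context "CT": fragment derives from the top strand; "GA": bottom strand.
## `projected` is the read in top-strand orientation.
readCombos <- function(seq) {
  rc <- revComp(seq)
  list(
    list(p = reduceCT(seq), img = "ct", context = "CT", projected = seq),
    list(p = reduceCT(rc),  img = "ct", context = "CT", projected = rc),
    list(p = reduceGA(rc),  img = "ga", context = "GA", projected = rc),
    list(p = reduceGA(seq), img = "ga", context = "GA", projected = seq)
  )
}

## convert positions in a joined image to contig coordinates; drops
## placements that do not fit inside one contig
catToContig <- function(starts, width, index) {
  ci <- findInterval(starts, index@cat_offset)
  st <- starts - index@cat_offset[ci] + 1L
  ok <- st >= 1L & st + width - 1L <= S4Vectors::width(index@genome)[ci]
  data.frame(chrom = names(index@genome)[ci[ok]], start = st[ok],
             cat_start = starts[ok], stringsAsFactors = FALSE)
}

## batched anchor lookup: pigeonhole seeds (max_mismatch + 1 disjoint
## 16-mers per pattern) are matched exactly for all reads at once with a
## PDict over each joined image, and candidate placements are verified at
## full length.  Returns a list (one per read) of hit data.frames.
batchAnchorHits <- function(seqs, index, max_mismatch = 3L) {
  n <- length(seqs)
  nseed <- max_mismatch + 1L
  hits_per_read <- vector("list", n)
  combos_all <- lapply(seqs, readCombos)
  min_w <- nseed * SEED_LEN

  for (img in c("ct", "ga")) {
    subject <- if (img == "ct") index@ct_cat else index@ga_cat
    seed_seq <- character(); seed_read <- integer()
    seed_combo <- integer(); seed_off <- integer()
    fallback <- list()  # (read, combo) pairs too short for seeding
    for (i in seq_len(n)) {
      for (k in seq_len(4L)) {
        cb <- combos_all[[i]][[k]]
        if (cb$img != img) next
        w <- nchar(cb$p)
        if (w < min_w) { fallback[[length(fallback) + 1L]] <- c(i, k); next }
        for (s in seq_len(nseed)) {
          off <- (s - 1L) * SEED_LEN
          seed_seq <- c(seed_seq, substr(cb$p, off + 1L, off + SEED_LEN))
          seed_read <- c(seed_read, i); seed_combo <- c(seed_combo, k)
          seed_off <- c(seed_off, off)
        }
      }
    }
    cand <- list()
    if (length(seed_seq)) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
      m <- Biostrings::matchPDict(pd, subject)
      nm <- S4Vectors::elementNROWS(m)
      which_hit <- which(nm > 0L)
      for (h in which_hit) {
        starts <- Biostrings::start(m[[h]]) - seed_off[h]
        key <- paste0(seed_read[h], "_", seed_combo[h])
        cand[[key]] <- c(cand[[key]], starts)
      }
    }
    ## verify candidates at full pattern length
    for (key in names(cand)) {
      ik <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
      i <- ik[1]; k <- ik[2]
      cb <- combos_all[[i]][[k]]
      w <- nchar(cb$p)
      starts <- sort(unique(cand[[key]]))
      starts <- starts[starts >= 1L & starts + w - 1L <= length(subject)]
      if (!length(starts)) next
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(cb$p), subject,
                                        starting.at = starts)
      keep <- mm <= max_mismatch
      if (!any(keep)) next
      conv <- catToContig(starts[keep], w, index)
      if (!nrow(conv)) next
      mm_keep <- mm[keep][match(conv$cat_start, starts[keep])]
      hits_per_read[[i]] <- rbind(hits_per_read[[i]], data.frame(
        chrom = conv$chrom, start = conv$start, end = conv$start + w - 1L,
        context = cb$context, projected = cb$projected, mm = mm_keep,
        combo = k, stringsAsFactors = FALSE))
    }
    ## short reads: direct per-contig search
    for (fk in fallback) {
      i <- fk[1]; k <- fk[2]
      cb <- combos_all[[i]][[k]]
      for (ch in names(index@genome)) {
        subj <- slot(index, img)[[ch]]
        if (length(subj) < nchar(cb$p)) next
        m <- Biostrings::matchPattern(Biostrings::DNAString(cb$p), subj,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (!length(m)) next
        st <- Biostrings::start(m)
        st <- st[st >= 1L & st + nchar(cb$p) - 1L <= length(subj)]
        if (!length(st)) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(cb$p), subj,
                                          starting.at = st)
        hits_per_read[[i]] <- rbind(hits_per_read[[i]], data.frame(
          chrom = ch, start = st, end = st + nchar(cb$p) - 1L,
          context = cb$context, projected = cb$projected, mm = mm,
          combo = k, stringsAsFactors = FALSE))
      }
    }
  }
  ## de-duplicate placements found by more than one combo
  lapply(hits_per_read, function(h) {
    if (is.null(h)) return(NULL)
    h <- h[h$mm <= max_mismatch, , drop = FALSE]
    h[!duplicated(h[, c("chrom", "start", "context")]), , drop = FALSE]
  })
}

## single-read lookup (used for mates within a window and by tests):
## direct mismatch-tolerant search, optionally restricted to one contig
## window and one combination
reducedHits <- function(seq, index, max_mismatch = 3L,
                        chroms = names(index@genome), window = NULL,
                        combos = 1:4) {
  pats <- readCombos(seq)
  out <- list()
  for (k in combos) {
    for (ch in chroms) {
      subj <- slot(index, pats[[k]]$img)[[ch]]
      off <- 0L
      if (!is.null(window)) {
        lo <- max(1L, window[1]); hi <- min(length(subj), window[2])
        if (hi - lo + 1L < nchar(seq)) next
        subj <- Biostrings::subseq(subj, lo, hi)
        off <- lo - 1L
      }
      m <- Biostrings::matchPattern(Biostrings::DNAString(pats[[k]]$p), subj,
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (!length(m)) next
      st <- Biostrings::start(m)
      st <- st[st >= 1L & st + nchar(seq) - 1L <= length(subj)]
      if (!length(st)) next
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pats[[k]]$p),
                                        subj, starting.at = st)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = st + off, end = st + off + nchar(seq) - 1L,
        context = pats[[k]]$context, projected = pats[[k]]$projected,
        mm = mm, combo = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  hits <- do.call(rbind, out)
  hits <- hits[hits$mm <= max_mismatch, , drop = FALSE]
  hits[!duplicated(hits[, c("chrom", "start", "context")]), , drop = FALSE]
}

#' Map trimmed TEPBAT read pairs with the unique-anchor rule
#'
#' The tag-side read (read 1) extends into unique flanking sequence and is
#' the anchor: it is searched genome-wide under the four bisulfite-reduced
#' combinations.  A pair is placed only if the anchor has exactly one
#' best-mismatch location (at most `max_mismatch` mismatches); ties and
#' misses discard the pair with a reason.  The primer-side mate is then
#' placed within the fragment-length bound on the consistent strand
#' combination; a mate that cannot be placed consistently discards the
#' pair.
#'
#' @param trimmed Output of [trimReadPairs()].
#' @param index A \linkS4class{ReducedIndex}.
#' @param max_mismatch Maximum (and tie-breaking) mismatch count.
#' @param fragment_range Allowed outer fragment span, as in the library.
#' @param primers Primer list (primer lengths enter the fragment-span
#'   computation because primer and tag bases were trimmed).
#' @return List with `alignments` (data.frame: read_id, tissue, chrom,
#'   start, end, context, projected, which) carrying one row per aligned
#'   read of each uniquely placed pair, `discards` (read_id, reason), and
#'   `counts` (named totals; pairs_in = pairs_unique + pairs_discarded).
#' @export
mapReadPairs <- function(trimmed, index, max_mismatch = 3L,
                         fragment_range = c(350L, 450L),
                         primers = tepbatPrimers()) {
  stopifnot(is(index, "ReducedIndex"))
  kept <- trimmed[trimmed$keep, , drop = FALSE]
  pre_excluded <- trimmed[!trimmed$keep, c("read_id", "reason")]
  aln <- list(); disc <- list()
  plen_of <- c("IAP-BS1" = nchar(primers$bs1), "IAP-BS2" = nchar(primers$bs2),
               none = 0L)
  ## only the random tetramer is genomic on the tag side; the 19-nt tag is
  ## synthetic, so the fragment extends 4 bp beyond the trimmed anchor
  ext <- TAG_TETRAMER
  slack <- 10L  # outer-span tolerance for quality-clipped reads

  anchor_hits <- batchAnchorHits(kept$seq1, index, max_mismatch)
  for (i in seq_len(nrow(kept))) {
    rid <- kept$read_id[i]
    hits <- anchor_hits[[i]]
    if (is.null(hits) || nrow(hits) == 0L) {
      disc[[length(disc) + 1L]] <- data.frame(read_id = rid, reason = "anchor_unmapped")
      next
    }
    best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
    if (nrow(best) > 1L) {
      disc[[length(disc) + 1L]] <- data.frame(read_id = rid, reason = "multi_hit")
      next
    }
    a <- best[1, ]
    ## mate: consistent combination and side.  Anchor combo 2 (rc of a
    ## top-strand fragment) pairs with mate combo 1 to its left; anchor
    ## combo 4 (top projection of a bottom-strand fragment) pairs with
    ## mate combo 3 to its right.
    plen <- plen_of[[kept$primer_detected[i]]]
    if (a$combo == 2L) {
      win <- c(a$end + ext - fragment_range[2] - slack, a$end + ext)
      want_combo <- 1L
    } else if (a$combo == 4L) {
      win <- c(a$start - ext, a$start - ext + fragment_range[2] + slack)
      want_combo <- 3L
    } else {
      disc[[length(disc) + 1L]] <- data.frame(read_id = rid,
                                              reason = "orientation_inconsistent")
      next
    }
    mh <- reducedHits(kept$seq2[i], index, max_mismatch,
                      chroms = a$chrom, window = win, combos = want_combo)
    okm <- NULL
    if (!is.null(mh) && nrow(mh)) {
      span <- if (want_combo == 1L)
        (a$end + ext) - (mh$start - plen) + 1L
      else
        (mh$end + plen) - (a$start - ext) + 1L
      okm <- mh[span >= fragment_range[1] - slack &
                span <= fragment_range[2] + slack, , drop = FALSE]
    }
    if (is.null(okm) || nrow(okm) == 0L) {
      disc[[length(disc) + 1L]] <- data.frame(read_id = rid, reason = "mate_inconsistent")
      next
    }
    m <- okm[which.min(okm$mm), ]
    aln[[length(aln) + 1L]] <- data.frame(
      read_id = rid, tissue = kept$tissue[i],
      chrom = c(a$chrom, m$chrom), start = c(a$start, m$start),
      end = c(a$end, m$end), context = c(a$context, m$context),
      projected = c(a$projected, m$projected),
      which = c("anchor", "mate"), stringsAsFactors = FALSE)
  }
  alignments <- do.call(rbind, aln)
  discards <- rbind(
    if (nrow(pre_excluded)) pre_excluded else NULL,
    if (length(disc)) do.call(rbind, disc) else NULL)
  n_unique <- if (is.null(alignments)) 0L else length(unique(alignments$read_id))
  counts <- c(pairs_in = nrow(trimmed), pairs_unique = n_unique,
              pairs_discarded = nrow(trimmed) - n_unique)
  if (!is.null(discards) && nrow(discards)) {
    by_reason <- table(discards$reason)
    counts <- c(counts, stats::setNames(as.integer(by_reason),
                                        paste0("discard_", names(by_reason))))
  }
  list(alignments = alignments, discards = discards, counts = counts)
}
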