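## IUPAC-aware mismatch count of `primer` against the start of many strings
mismatchesAtStart <- function(strings, primer) {
  np <- nchar(primer)
  out <- rep(NA_integer_, length(strings))
  ok <- nchar(strings) >= np
  if (!any(ok)) return(out)
  m <- do.call(rbind, strsplit(substr(strings[ok], 1L, np), ""))
  pv <- strsplit(primer, "")[[1]]
  allowed <- Biostrings::IUPAC_CODE_MAP[pv]
  cmp <- vapply(seq_len(np), function(j) !stringIn(m[, j], allowed[j]),
                logical(sum(ok)))
  mm <- if (sum(ok) == 1L) sum(cmp) else rowSums(cmp)
  out[ok] <- as.integer(mm)
  out
}

stringIn <- function(bases, allowed) {
  vapply(bases, function(b) grepl(b, allowed, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

## remove trailing bases with Phred quality below `threshold`
qualityClip <- function(seq, qual, threshold) {
  q <- utf8ToInt(qual) - 33L
  keep <- which(q >= threshold)
  n <- if (length(keep)) max(keep) else 0L
  c(substr(seq, 1L, n), substr(qual, 1L, n))
}

#' Trim tag, primer and low-quality bases from TEPBAT read pairs
#'
#' Read 1 starting with the 19-nt tag (at most `max_tag_mismatch`
#' mismatches) loses the tag plus the 4 random-tetramer bases; read 2
#' starting with a known IAP primer (at most `max_primer_mismatch`
#' IUPAC-aware mismatches) loses the primer, and which primer is recorded.
#' 3' bases with quality below `quality_threshold` are removed.  Pairs with
#' neither tag nor primer, or empty after trimming, are flagged for
#' exclusion with a reason.
#'
#' @param reads data.frame with read_id, tissue, read1, qual1, read2, qual2
#'   (as produced by [simulateTepbatReads()] / [readTepbatFastq()]).
#' @param primers Primer list as [tepbatPrimers()].
#' @param quality_threshold Phred threshold for 3' clipping.
#' @param max_tag_mismatch,max_primer_mismatch Detection tolerances.
#' @return data.frame: read_id, tissue, seq1, qual1, seq2, qual2 (trimmed),
#'   tag_detected, primer_detected ("IAP-BS1"/"IAP-BS2"/"none"), keep,
#'   reason.
#' @export
trimReadPairs <- function(reads, primers = tepbatPrimers(),
                          quality_threshold = 20L,
                          max_tag_mismatch = 1L, max_primer_mismatch = 2L) {
  assertIupac(unlist(primers))
  tag <- primers$tag
  tag_mm <- mismatchesAtStart(reads$read1, tag)
  tag_detected <- !is.na(tag_mm) & tag_mm <= max_tag_mismatch

  mm1 <- mismatchesAtStart(reads$read2, primers$bs1)
  mm2 <- mismatchesAtStart(reads$read2, primers$bs2)
  p1 <- !is.na(mm1) & mm1 <= max_primer_mismatch
  p2 <- !is.na(mm2) & mm2 <= max_primer_mismatch
  primer_detected <- ifelse(p2 & (!p1 | mm2 <= mm1), "IAP-BS2",
                            ifelse(p1, "IAP-BS1", "none"))

  n <- nrow(reads)
  seq1 <- reads$read1; qual1 <- reads$qual1
  seq2 <- reads$read2; qual2 <- reads$qual2
  cut1 <- nchar(tag) + TAG_TETRAMER
  seq1[tag_detected] <- substr(seq1[tag_detected], cut1 + 1L, nchar(seq1[tag_detected]))
  qual1[tag_detected] <- substr(qual1[tag_detected], cut1 + 1L, nchar(qual1[tag_detected]))
  plen <- ifelse(primer_detected == "IAP-BS1", nchar(primers$bs1),
                 ifelse(primer_detected == "IAP-BS2", nchar(primers$bs2), 0L))
  has_p <- plen > 0L
  seq2[has_p] <- substr(seq2[has_p], plen[has_p] + 1L, nchar(seq2[has_p]))
  qual2[has_p] <- substr(qual2[has_p], plen[has_p] + 1L, nchar(qual2[has_p]))

  for (i in seq_len(n)) {
    a <- qualityClip(seq1[i], qual1[i], quality_threshold)
    seq1[i] <- a[1]; qual1[i] <- a[2]
    b <- qualityClip(seq2[i], qual2[i], quality_threshold)
    seq2[i] <- b[1]; qual2[i] <- b[2]
  }

  keep <- rep(TRUE, n); reason <- rep(NA_character_, n)
  no_both <- !tag_detected & primer_detected == "none"
  keep[no_both] <- FALSE; reason[no_both] <- "no_tag_no_primer"
  empty <- keep & (nchar(seq1) == 0L | nchar(seq2) == 0L)
  keep[empty] <- FALSE; reason[empty] <- "empty_after_trim"

  data.frame(read_id = reads$read_id, tissue = reads$tissue,
             seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
             tag_detected = tag_detected, primer_detected = primer_detected,
             keep = keep, reason = reason, stringsAsFactors = FALSE)
}
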