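#' TEPBAT tag and IAP primer sequences
#'
#' The library design uses a tag-plus-random primer for first-strand
#' synthesis on bisulfite-converted DNA and one of two IAP-specific primers
#' for target amplification.  `IAP-BS1` (19 nt, reverse orientation) primes
#' near the 5' end of the LTR and amplifies towards the upstream flank;
#' `IAP-BS2` (30 nt, forward orientation) primes near the 3' end and
#' amplifies towards the downstream flank.  Both primers are written as they
#' read on the converted template strand they anneal to; `IAP-BS1` carries
#' one IUPAC W (A or T).
#'
#' @return Named list with elements `tag` (19 nt specific tag; the full
#'   first-strand primer is `tag` followed by an `NNNN` random tetramer),
#'   `bs1` and `bs2` (IAP-specific PCR primers).
#' @examples
#' tepbatPrimers()
#' @export
tepbatPrimers <- function() {
  list(
    tag = "GCAGTGAACTGACTACAGG",
    bs1 = "GGGGAAGGTAGAGTATAWG",
    bs2 = "GGTTTTTGAAGATGTAAGTAATAAAGTTTT"
  )
}

## number of random-tetramer bases following the tag in read 1
TAG_TETRAMER <- 4L

#' Count IUPAC-aware mismatches of a primer at a fixed position
#'
#' Ambiguity codes in the primer (e.g. W = A/T) match any of their bases;
#' the subject is treated as concrete {A,C,G,T}.
#'
#' @param primer Character scalar, IUPAC DNA.
#' @param subject Character scalar, concrete DNA.
#' @param at 1-based start of the primer on the subject.
#' @return Integer mismatch count, or NA if the primer overruns the subject.
#' @keywords internal
primerMismatches <- function(primer, subject, at = 1L) {
  np <- nchar(primer)
  if (at < 1L || at + np - 1L > nchar(subject)) return(NA_integer_)
  sub <- substr(subject, at, at + np - 1L)
  pv <- strsplit(primer, "")[[1]]
  sv <- strsplit(sub, "")[[1]]
  sum(!iupacBaseMatch(pv, sv))
}

## vectorised: does IUPAC code p match concrete base s?
iupacBaseMatch <- function(p, s) {
  map <- Biostrings::IUPAC_CODE_MAP
  allowed <- map[p]
  allowed[is.na(allowed)] <- ""
  mapply(function(a, b) grepl(b, a, fixed = TRUE), allowed, s, USE.NAMES = FALSE)
}

#' Check that a string is valid IUPAC DNA
#' @keywords internal
assertIupac <- function(x, what = "primer") {
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", x)
  if (!all(ok)) stop(what, " contains non-IUPAC characters: ", x[!ok][1])
  invisible(x)
}

#' Reduce DNA to a bisulfite alphabet
#'
#' `reduceCT()` replaces every C by T (the fully converted top strand);
#' `reduceGA()` replaces every G by A (the mirror reduction used for reads
#' and genome when the fragment derives from the bottom strand).
#'
#' @param x Character vector or XStringSet of DNA.
#' @return Same type as the input, reduced.
#' @examples
#' reduceCT("ACGT")  # "ATGT"
#' reduceGA("ACGT")  # "ACAT"
#' @export
reduceCT <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) {
    return(Biostrings::chartr("C", "T", x))
  }
  chartr("C", "T", x)
}

#' @rdname reduceCT
#' @export
reduceGA <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) {
    return(Biostrings::chartr("G", "A", x))
  }
  chartr("G", "A", x)
}

## reverse complement for plain character vectors (ACGTN alphabet)
revComp <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))),
         character(1), USE.NAMES = FALSE)
}
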