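#' Call per-CpG methylation from uniquely placed reads
#'
#' For every aligned read base overlapping a genomic CpG dyad on the read's
#' informative strand, a C (top-strand context) or G (bottom-strand
#' context, projected) increments the methylated count and a T
#' (respectively A) the unmethylated count; other bases are ignored.
#' Calls from the two strands of a dyad are collapsed onto the position of
#' the C on the + strand, so downstream aggregation is strand-free.
#'
#' @param alignments Alignment table from [mapReadPairs()] (`$alignments`).
#' @param genome Named [Biostrings::DNAStringSet] used for CpG context.
#' @param by_tissue Split calls by the `tissue` column (default TRUE when
#'   present).
#' @return data.frame: (tissue,) chrom, pos (1-based position of the
#'   + strand C), meth, unmeth.  `meth + unmeth` equals the number of
#'   informative read bases covering the site.
#' @export
callMethylation <- function(alignments, genome, by_tissue = TRUE) {
  if (is.null(alignments) || nrow(alignments) == 0L)
    return(data.frame(tissue = character(), chrom = character(),
                      pos = integer(), meth = integer(), unmeth = integer()))
  chrom_len <- stats::setNames(S4Vectors::width(genome), names(genome))
  if (any(alignments$end > chrom_len[alignments$chrom] | alignments$start < 1L))
    stop("alignment past contig end")
  cpg_c <- lapply(genome, function(s)
    Biostrings::start(Biostrings::matchPattern("CG", s)))

  has_tissue <- by_tissue && "tissue" %in% names(alignments)
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    ch <- alignments$chrom[i]
    st <- alignments$start[i]; en <- alignments$end[i]
    v <- strsplit(alignments$projected[i], "")[[1]]
    cp <- cpg_c[[ch]]
    if (alignments$context[i] == "CT") {
      p <- cp[cp >= st & cp <= en]
      if (!length(p)) next
      b <- v[p - st + 1L]
      informative <- b %in% c("C", "T")
      if (!any(informative)) next
      rows[[i]] <- data.frame(
        tissue = if (has_tissue) alignments$tissue[i] else NA_character_,
        chrom = ch, pos = p[informative],
        meth = as.integer(b[informative] == "C"), stringsAsFactors = FALSE)
    } else {
      g <- cp + 1L
      p <- g[g >= st & g <= en]
      if (!length(p)) next
      b <- v[p - st + 1L]
      informative <- b %in% c("G", "A")
      if (!any(informative)) next
      rows[[i]] <- data.frame(
        tissue = if (has_tissue) alignments$tissue[i] else NA_character_,
        chrom = ch, pos = p[informative] - 1L,
        meth = as.integer(b[informative] == "G"), stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    return(data.frame(tissue = character(), chrom = character(),
                      pos = integer(), meth = integer(), unmeth = integer()))
  key <- paste(calls$tissue, calls$chrom, calls$pos, sep = "\r")
  agg <- rowsum(cbind(meth = calls$meth, n = 1L), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(tissue = parts[, 1], chrom = parts[, 2],
                    pos = as.integer(parts[, 3]),
                    meth = as.integer(agg[, "meth"]),
                    unmeth = as.integer(agg[, "n"] - agg[, "meth"]),
                    stringsAsFactors = FALSE)
  if (!has_tissue) out$tissue <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write / read a CpG-report table
#'
#' Tab-separated, 1-based position of the + strand C, columns chrom, pos,
#' strand, meth, unmeth, context ("CpG") — the cytosine-report dialect of
#' standard bisulfite callers.
#'
#' @param calls data.frame from [callMethylation()] (one tissue).
#' @param file Path.
#' @return `readCpgReport` returns the calls data.frame.
#' @export
writeCpgReport <- function(calls, file) {
  d <- data.frame(chrom = calls$chrom, pos = calls$pos, strand = "+",
                  meth = calls$meth, unmeth = calls$unmeth, context = "CpG")
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeCpgReport
#' @export
readCpgReport <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         col.names = c("chrom", "pos", "strand", "meth",
                                       "unmeth", "context"),
                         stringsAsFactors = FALSE)
  data.frame(chrom = d$chrom, pos = as.integer(d$pos),
             meth = as.integer(d$meth), unmeth = as.integer(d$unmeth),
             stringsAsFactors = FALSE)
}
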