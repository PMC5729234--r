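#' Write and read the repeat annotation table
#'
#' The native dialect is a RepeatMasker-like TSV with 1-based inclusive
#' coordinates (chrom, start, end, strand, subfamily, class, feature,
#' element_id, copy_id plus any extra columns).  `writeAnnotationBed()`
#' emits BED6 (0-based half-open, name = copy_id, score = 0).
#'
#' @param annotation GRanges.
#' @param file Path.
#' @return `readAnnotation` returns a GRanges.
#' @export
writeAnnotation <- function(annotation, file) {
  mc <- as.data.frame(S4Vectors::mcols(annotation))
  d <- cbind(data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    strand = as.character(GenomicRanges::strand(annotation)),
    stringsAsFactors = FALSE), mc)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  asRepeatGRanges(d)
}

#' @rdname writeAnnotation
#' @export
writeAnnotationBed <- function(annotation, file) {
  mc <- S4Vectors::mcols(annotation)
  name <- if ("copy_id" %in% names(mc)) mc$copy_id else "."
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(annotation),
    name = name, score = 0L,
    strand = as.character(GenomicRanges::strand(annotation)))
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
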