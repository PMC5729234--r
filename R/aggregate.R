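#' Aggregate CpG calls into per-LTR methylation levels
#'
#' For every annotated LTR copy, collects the CpG sites within its span,
#' computes per-site levels meth/(meth+unmeth), the per-copy mean level
#' (unweighted mean over covered sites by default, or the pooled-calls
#' ratio), and the total call count (summed depth over CpG sites).  A copy
#' with zero covered sites gets an undefined (NA) mean and fails the
#' filter.
#'
#' @param cpg_report data.frame chrom, pos (1-based), meth, unmeth for one
#'   tissue (optionally a `tissue` column; then aggregation is per tissue).
#' @param annotation GRanges with mcols `copy_id`, `class`, `subfamily`,
#'   `feature` (only `class == "ltr"` rows are aggregated), or any GRanges
#'   with a `copy_id` column.
#' @param statistic "mean_of_sites" (default) or "pooled" for the
#'   pooled-calls ratio sum(meth)/sum(meth+unmeth).
#' @param min_calls Call-count filter threshold recorded in `pass_filter`.
#' @param tissue Tissue label to attach when the report has no tissue
#'   column.
#' @return data.frame: copy_id, tissue, subfamily, feature, chrom, start,
#'   end, n_cpg_covered, total_calls, mean_level, pass_filter, bin
#'   (low/medium/high, NA when the filter fails or the mean is undefined).
#' @export
aggregateLtrMethylation <- function(cpg_report, annotation,
                                    statistic = c("mean_of_sites", "pooled"),
                                    min_calls = 20L,
                                    tissue = NA_character_) {
  statistic <- match.arg(statistic)
  if (!"tissue" %in% names(cpg_report)) cpg_report$tissue <- tissue
  mc <- S4Vectors::mcols(annotation)
  ltr <- if ("class" %in% names(mc)) annotation[mc$class == "ltr"] else annotation
  lmc <- S4Vectors::mcols(ltr)
  getcol <- function(col) if (col %in% names(lmc)) lmc[[col]] else NA
  out <- list()
  for (t in unique(cpg_report$tissue)) {
    rep_t <- cpg_report[cpg_report$tissue %in% t, , drop = FALSE]
    sites <- GenomicRanges::GRanges(rep_t$chrom,
                                    IRanges::IRanges(rep_t$pos, rep_t$pos))
    ov <- GenomicRanges::findOverlaps(ltr, sites, ignore.strand = TRUE)
    n <- length(ltr)
    n_cpg <- integer(n); total <- integer(n); mlev <- rep(NA_real_, n)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      depth <- rep_t$meth[s] + rep_t$unmeth[s]
      lev <- rep_t$meth[s] / depth
      n_cpg <- as.integer(tabulate(q, nbins = n))
      tot_by <- rowsum(depth, q)
      total[as.integer(rownames(tot_by))] <- as.integer(tot_by[, 1])
      fq <- factor(q, levels = seq_len(n))
      mlev <- if (statistic == "mean_of_sites")
        as.numeric(tapply(lev, fq, mean))
      else
        as.numeric(tapply(rep_t$meth[s], fq, sum)) /
          as.numeric(tapply(depth, fq, sum))
    }
    pass <- total >= min_calls & n_cpg >= 1L
    out[[length(out) + 1L]] <- data.frame(
      copy_id = lmc$copy_id, tissue = t,
      subfamily = getcol("subfamily"), feature = getcol("feature"),
      chrom = as.character(GenomicRanges::seqnames(ltr)),
      start = GenomicRanges::start(ltr), end = GenomicRanges::end(ltr),
      n_cpg_covered = n_cpg, total_calls = total, mean_level = mlev,
      pass_filter = pass,
      bin = ifelse(pass & !is.na(mlev), binMethylation(ifelse(is.na(mlev), 0, mlev)),
                   NA_character_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Apply the minimum-call-count filter
#'
#' Retains LTR records with at least `min_calls` CpG methylation calls
#' (summed sequencing depth over the copy's CpG sites); 19 calls are
#' excluded, 20 retained.
#'
#' @param records data.frame from [aggregateLtrMethylation()].
#' @param min_calls Threshold (default 20).
#' @return The passing subset, with attribute `n_excluded`.
#' @export
filterLtrs <- function(records, min_calls = 20L) {
  if (min_calls < 0L) stop("min_calls must be non-negative")
  keep <- records$total_calls >= min_calls & records$n_cpg_covered >= 1L
  out <- records[keep, , drop = FALSE]
  out$pass_filter <- rep(TRUE, nrow(out))
  out$bin <- binMethylation(out$mean_level)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Bin a methylation level into low / medium / high
#'
#' low: level <= 0.2; high: level > 0.8; medium: (0.2, 0.8].
#'
#' @param mean_level Numeric vector in [0, 1].
#' @return Character vector of bins.
#' @examples
#' binMethylation(c(0.2, 0.5, 0.81))  # low medium high
#' @export
binMethylation <- function(mean_level) {
  if (any(mean_level < 0 | mean_level > 1, na.rm = TRUE))
    stop("methylation level outside [0,1]")
  ifelse(is.na(mean_level), NA_character_,
         ifelse(mean_level <= 0.2, "low",
                ifelse(mean_level > 0.8, "high", "medium")))
}

#' Per-copy table restricted to copies passing the filter in all tissues
#'
#' Intersects the per-tissue records on `copy_id`, keeping only copies that
#' pass the call-count filter in every tissue, and reports per-copy levels
#' and bins side by side.  Per-subfamily analyzed-vs-genomic copy counts
#' are attached as attribute `subfamily_counts`.
#'
#' @param records data.frame from [aggregateLtrMethylation()] covering at
#'   least two tissues.
#' @param tissues Tissues to intersect (default: all present).
#' @param min_calls Filter threshold.
#' @return data.frame: copy_id, subfamily, feature, then `level_<tissue>`
#'   and `bin_<tissue>` per tissue.
#' @export
jointTissueTable <- function(records, tissues = NULL, min_calls = 20L) {
  if (is.null(tissues)) tissues <- unique(records$tissue)
  if (length(tissues) < 2L) stop("at least two tissues required")
  if (!all(tissues %in% records$tissue))
    stop("tissue absent from records: ",
         paste(setdiff(tissues, records$tissue), collapse = ", "))
  per <- lapply(tissues, function(t)
    filterLtrs(records[records$tissue == t, , drop = FALSE], min_calls))
  ids <- Reduce(intersect, lapply(per, `[[`, "copy_id"))
  base <- per[[1]][match(ids, per[[1]]$copy_id),
                   c("copy_id", "subfamily", "feature"), drop = FALSE]
  for (k in seq_along(tissues)) {
    d <- per[[k]][match(ids, per[[k]]$copy_id), ]
    base[[paste0("level_", tissues[k])]] <- d$mean_level
    base[[paste0("bin_", tissues[k])]] <- d$bin
  }
  rownames(base) <- NULL
  genomic <- table(records$subfamily[records$tissue == tissues[1]])
  analyzed <- table(base$subfamily)
  sf <- sort(unique(records$subfamily))
  attr(base, "subfamily_counts") <- data.frame(
    subfamily = sf,
    genomic = as.integer(genomic[sf]),
    analyzed = as.integer(ifelse(is.na(analyzed[sf]), 0L, analyzed[sf])),
    stringsAsFactors = FALSE)
  base
}

#' Write the per-copy methylation table
#'
#' Tab-separated per-copy layout (copy id, coordinates, subfamily, feature,
#' per-tissue level and bin, total calls).
#' @param records data.frame from [aggregateLtrMethylation()].
#' @param file Path.
#' @export
writeLtrMethylation <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
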