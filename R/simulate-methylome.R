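#' CpG dyad positions of annotated copies
#'
#' Positions (1-based, of the C on the + strand) of CpG dinucleotides inside
#' each annotated range.  CpG dyads are strand-symmetric so element
#' orientation is irrelevant.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param annotation GRanges of copies.
#' @return data.frame with `copy_id`, `chrom`, `pos`.
#' @export
copyCpGSites <- function(genome, annotation) {
  cpg_by_chrom <- lapply(genome, function(s)
    Biostrings::start(Biostrings::matchPattern("CG", s)))
  out <- vector("list", length(annotation))
  ch <- as.character(GenomicRanges::seqnames(annotation))
  st <- GenomicRanges::start(annotation)
  en <- GenomicRanges::end(annotation)
  ids <- S4Vectors::mcols(annotation)$copy_id
  for (i in seq_along(annotation)) {
    p <- cpg_by_chrom[[ch[i]]]
    p <- p[p >= st[i] & p <= en[i] - 1L]
    if (length(p))
      out[[i]] <- data.frame(copy_id = ids[i], chrom = ch[i], pos = p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assign a ground-truth methylome to planted copies
#'
#' Each LTR copy gets a copy-level mean methylation per tissue:
#' hypomethylated copies (in their designated tissue) draw from
#' `hypo_max * Beta(hypo_shape)` so the level lies in [0, hypo_max];
#' all other copy-tissue combinations draw from `Beta(hyper_shape)`
#' (default mean 0.9).  Per-CpG truth equals the copy mean, optionally
#' jittered by `cpg_jitter_sd` (truncated to [0,1]).  Assignment is
#' tissue-specific: a copy hypomethylated in sperm only is drawn from the
#' high distribution in tail.
#'
#' @param sim Output of [buildGenome()] (list with `genome`, `annotation`),
#'   or a GRanges annotation if `genome` is supplied.
#' @param config A \linkS4class{SimConfig}.
#' @param genome Optional genome when `sim` is a GRanges.
#' @return Object of class `TruthMethylome`: list with `levels`
#'   (copy_id, tissue, level, clade) and `sites`
#'   (copy_id, tissue, chrom, pos, prob).
#' @export
assignMethylome <- function(sim, config, genome = NULL) {
  if (is(sim, "GRanges")) {
    annotation <- sim
    if (is.null(genome)) stop("genome required when annotation is passed directly")
  } else {
    annotation <- sim$annotation
    genome <- sim$genome
  }
  stopifnot(is(config, "SimConfig"))
  ltr <- annotation[S4Vectors::mcols(annotation)$class == "ltr"]
  if (length(ltr) == 0L) stop("empty copy list")
  tissues <- config@tissues
  set.seed(deriveSeed(config@seed, "methylome"))

  cpg <- copyCpGSites(genome, ltr)
  mc <- S4Vectors::mcols(ltr)
  hypo_in <- strsplit(ifelse(is.na(mc$hypo_tissues), "", mc$hypo_tissues), ",")

  lev <- list(); sites <- list()
  for (t in tissues) {
    is_hypo <- vapply(hypo_in, function(h) t %in% h, logical(1))
    n <- length(ltr)
    level <- numeric(n)
    level[!is_hypo] <- stats::rbeta(sum(!is_hypo), config@hyper_shape[1],
                                    config@hyper_shape[2])
    level[is_hypo] <- config@hypo_max *
      stats::rbeta(sum(is_hypo), config@hypo_shape[1], config@hypo_shape[2])
    lev[[t]] <- data.frame(copy_id = mc$copy_id, tissue = t, level = level,
                           clade = ifelse(is_hypo, "hypo", "hyper"),
                           stringsAsFactors = FALSE)
    s <- cpg
    if (!is.null(s) && nrow(s)) {
      s$tissue <- t
      s$prob <- level[match(s$copy_id, mc$copy_id)]
      if (config@cpg_jitter_sd > 0) {
        s$prob <- pmin(1, pmax(0, s$prob +
          stats::rnorm(nrow(s), 0, config@cpg_jitter_sd)))
      }
      sites[[t]] <- s[, c("copy_id", "tissue", "chrom", "pos", "prob")]
    }
  }
  out <- list(levels = do.call(rbind, lev), sites = do.call(rbind, sites))
  class(out) <- c("TruthMethylome", "list")
  out
}

#' @export
print.TruthMethylome <- function(x, ...) {
  cat("TruthMethylome:", length(unique(x$levels$copy_id)), "copies x",
      length(unique(x$levels$tissue)), "tissues;",
      sum(x$levels$clade == "hypo"), "copy-tissue pairs hypomethylated\n")
  invisible(x)
}
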