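#' Integer percent, half away from zero
#'
#' The rounding convention of copy-count percentages in figure legends:
#' round(100 * count / total) to the nearest integer, halves away from
#' zero (so 23 of 43 is 53, 36 of 43 is 84).
#'
#' @param count,total Non-negative counts, `0 <= count <= total`,
#'   `total > 0`.
#' @return Integer percent.
#' @examples
#' percentReport(23, 43)  # 53
#' @export
percentReport <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must be within [0, total]")
  x <- 100 * count / total
  as.integer(floor(x + 0.5))
}

#' Methylation-bin counts of a joint table
#'
#' Counts copies per low/medium/high bin for a tissue, and a finer
#' five-way split of the level range for stacked-bar style summaries.
#'
#' @param joint Joint table from [jointTissueTable()].
#' @param tissue Tissue label.
#' @return List with `bins` (named counts low/medium/high, summing to the
#'   table size), `percent` (integer percents), and `five_way` (counts in
#'   [0,0.2], (0.2,0.4], (0.4,0.6], (0.6,0.8], (0.8,1]).
#' @export
binCounts <- function(joint, tissue) {
  lev <- joint[[paste0("level_", tissue)]]
  if (is.null(lev)) stop("tissue absent: ", tissue)
  b <- factor(binMethylation(lev), levels = c("low", "medium", "high"))
  bins <- table(b)
  five <- table(cut(lev, breaks = c(-0.001, 0.2, 0.4, 0.6, 0.8, 1),
                    labels = c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1")))
  list(bins = stats::setNames(as.integer(bins), names(bins)),
       percent = stats::setNames(percentReport(as.integer(bins), length(lev)),
                                 names(bins)),
       five_way = stats::setNames(as.integer(five), names(five)),
       n = length(lev))
}

#' Subfamily distribution of hypomethylated copies
#'
#' @param hypo data.frame of hypomethylated copies (bin low in the chosen
#'   tissue) with a `subfamily` column, or a character vector of
#'   subfamilies.
#' @return data.frame subfamily, count, percent (integer, half away from
#'   zero), ordered by decreasing count.  Empty input gives an empty
#'   distribution.
#' @examples
#' subfamilyDistribution(rep(c("IAPEY", "IAPLTR2a2", "other"), c(23, 13, 7)))
#' @export
subfamilyDistribution <- function(hypo) {
  sf <- if (is.character(hypo)) hypo else hypo$subfamily
  if (length(sf) == 0L)
    return(data.frame(subfamily = character(), count = integer(),
                      percent = integer(), stringsAsFactors = FALSE))
  cnt <- sort(table(sf), decreasing = TRUE)
  data.frame(subfamily = names(cnt), count = as.integer(cnt),
             percent = percentReport(as.integer(cnt), length(sf)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-by-two enrichment of a feature among hypomethylated copies
#'
#' Builds the contingency table (hypomethylated vs not) x (feature vs
#' rest) over the joint-table universe and tests association with a
#' two-sided Fisher exact test.  The odds ratio is the sample odds ratio
#' a*d / (b*c) (infinite or undefined on zero margins).
#'
#' @param joint Joint table from [jointTissueTable()] (needs `feature` and
#'   `bin_<tissue>` columns), or NULL when `counts` is given.
#' @param tissue Tissue label.
#' @param feature Feature level tested (e.g. "solo").
#' @param counts Optional c(a, b, c, d) to test a pre-tabulated 2x2
#'   (a = hypo&feature, b = hypo&rest, c = not-hypo&feature,
#'   d = not-hypo&rest).
#' @return List of class `EnrichmentResult`: category, a, b, c, d,
#'   odds_ratio, p_value, flag.
#' @export
featureEnrichment <- function(joint = NULL, tissue = NULL, feature = "solo",
                              counts = NULL) {
  if (is.null(counts)) {
    bin <- joint[[paste0("bin_", tissue)]]
    if (is.null(bin)) stop("tissue absent: ", tissue)
    hypo <- bin == "low"
    isf <- joint$feature == feature
    counts <- c(sum(hypo & isf), sum(hypo & !isf),
                sum(!hypo & isf), sum(!hypo & !isf))
  }
  a <- counts[1]; b <- counts[2]; cc <- counts[3]; d <- counts[4]
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  zero_margin <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (zero_margin) {
    res <- list(category = feature, a = a, b = b, c = cc, d = d,
                odds_ratio = NA_real_, p_value = 1, flag = "zero_margin")
  } else {
    p <- stats::fisher.test(tab)$p.value
    or <- (a * d) / (b * cc)   # may be Inf when b or c is 0
    res <- list(category = feature, a = a, b = b, c = cc, d = d,
                odds_ratio = or, p_value = min(1, p), flag = "ok")
  }
  class(res) <- c("EnrichmentResult", "list")
  res
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult [", x$category, "]: 2x2 = (", x$a, ",", x$b, ";",
      x$c, ",", x$d, "), OR =", format(x$odds_ratio, digits = 3),
      ", p =", format(x$p_value, digits = 3),
      if (!is.null(x$q_value)) paste(", q =", format(x$q_value, digits = 3)),
      "\n")
  invisible(x)
}

#' Per-subfamily methylation-level summaries
#'
#' Median, quartiles and n per subfamily and tissue (box-plot summaries).
#'
#' @param joint Joint table from [jointTissueTable()].
#' @param tissues Tissues to summarise (default: all `level_` columns).
#' @return data.frame subfamily, tissue, n, q1, median, q3.
#' @export
subfamilySummary <- function(joint, tissues = NULL) {
  if (is.null(tissues))
    tissues <- sub("^level_", "", grep("^level_", names(joint), value = TRUE))
  out <- list()
  for (t in tissues) {
    lev <- joint[[paste0("level_", t)]]
    for (sf in sort(unique(joint$subfamily))) {
      x <- lev[joint$subfamily == sf]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        subfamily = sf, tissue = t, n = length(x),
        q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Methylation concordance of the two LTRs of each provirus
#'
#' For elements whose 5' and 3' LTRs both pass the filter, reports the
#' level pair per tissue and counts discordant pairs (one LTR <= 0.2, the
#' other > 0.8).
#'
#' @param joint Joint table from [jointTissueTable()].
#' @param pairs data.frame from [elementLtrPairs()].
#' @param tissue Tissue label.
#' @return List with `table` (element_id, level_5p, level_3p),
#'   `n_discordant`, and `correlation` (Pearson r, NA for < 3 pairs).
#' @export
ltrPairConcordance <- function(joint, pairs, tissue) {
  lev <- joint[[paste0("level_", tissue)]]
  if (is.null(lev)) stop("tissue absent: ", tissue)
  l5 <- lev[match(pairs$five_prime, joint$copy_id)]
  l3 <- lev[match(pairs$three_prime, joint$copy_id)]
  ok <- !is.na(l5) & !is.na(l3)
  tab <- data.frame(element_id = pairs$element_id[ok],
                    level_5p = l5[ok], level_3p = l3[ok],
                    stringsAsFactors = FALSE)
  disc <- with(tab, (level_5p <= 0.2 & level_3p > 0.8) |
                    (level_3p <= 0.2 & level_5p > 0.8))
  list(table = tab, n_discordant = sum(disc),
       correlation = if (nrow(tab) >= 3L)
         stats::cor(tab$level_5p, tab$level_3p) else NA_real_)
}
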