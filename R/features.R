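#' Annotate LTR copies as 5' LTR, 3' LTR or solo
#'
#' An LTR adjacent (within `gap_tolerance`) to an internal fragment on the
#' same strand is a provirus LTR: it is `five_prime` when the internal
#' sequence lies on its element-3' side (genomic right for + strand,
#' genomic left for - strand) and `three_prime` otherwise.  The two LTRs
#' flanking the same contiguous internal run share an `element_id`; all
#' other LTRs are `solo`.  An LTR with internal fragments on both sides
#' that cannot be paired is left `unassigned` with a warning.
#'
#' Internal fragments are recognised by `class == "internal"` when a class
#' column exists, otherwise by the "-int" subfamily-name suffix convention
#' of RepeatMasker.
#'
#' @param annotation GRanges (or data.frame with chrom/start/end/strand/
#'   subfamily columns, including the UCSC RepeatMasker dialect genoName/
#'   genoStart/genoEnd/repName) sorted or not.
#' @param gap_tolerance Maximum gap (bp) between an LTR and its internal
#'   run (default 1000; annotation pipelines frequently split elements).
#' @return The GRanges with mcols `feature` and `element_id` (re)assigned.
#' @export
annotateLtrFeatures <- function(annotation, gap_tolerance = 1000L) {
  gr <- asRepeatGRanges(annotation)
  mc <- S4Vectors::mcols(gr)
  if (!"class" %in% names(mc))
    mc$class <- ifelse(grepl("-int$|_int$", mc$subfamily), "internal", "ltr")
  o <- order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  gr <- gr[o]; mc <- mc[o, , drop = FALSE]

  n <- length(gr)
  feature <- rep(NA_character_, n)
  element_id <- rep(NA_character_, n)
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sd <- as.character(GenomicRanges::strand(gr))
  is_ltr <- mc$class == "ltr"
  elem_counter <- 0L

  ## walk each chromosome, grouping runs LTR - internal(+) - LTR
  for (chrom in unique(ch)) {
    idx <- which(ch == chrom)
    i <- 1L
    while (i <= length(idx)) {
      a <- idx[i]
      if (!is_ltr[a]) { i <- i + 1L; next }
      ## look ahead: internal run then closing LTR, same strand, gaps within
      ## tolerance
      j <- i + 1L
      run <- integer()
      while (j <= length(idx)) {
        b <- idx[j]
        prev <- if (length(run)) run[length(run)] else a
        if (!is_ltr[b] && sd[b] == sd[a] &&
            st[b] - en[prev] - 1L <= gap_tolerance) {
          run <- c(run, b); j <- j + 1L
        } else break
      }
      closed <- length(run) > 0L && j <= length(idx) &&
        is_ltr[idx[j]] && sd[idx[j]] == sd[a] &&
        st[idx[j]] - en[run[length(run)]] - 1L <= gap_tolerance
      if (closed) {
        b <- idx[j]
        elem_counter <- elem_counter + 1L
        eid <- sprintf("element_%03d", elem_counter)
        if (sd[a] == "+") { feature[a] <- "five_prime"; feature[b] <- "three_prime" }
        else              { feature[a] <- "three_prime"; feature[b] <- "five_prime" }
        element_id[c(a, run, b)] <- eid
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  ## remaining LTRs: solo unless an unpaired internal sits within tolerance
  ## on both sides (ambiguous)
  unass <- which(is_ltr & is.na(feature))
  for (a in unass) {
    near <- which(ch == ch[a] & !is_ltr & sd == sd[a] & is.na(element_id) &
                  ((st > en[a] & st - en[a] - 1L <= gap_tolerance) |
                   (en < st[a] & st[a] - en - 1L <= gap_tolerance)))
    if (length(near) == 0L) { feature[a] <- "solo"; next }
    left <- any(en[near] < st[a]); right <- any(st[near] > en[a])
    if (left && right) {
      feature[a] <- "unassigned"
      warning("LTR at ", ch[a], ":", st[a],
              " has internal fragments on both sides; feature unassigned")
    } else if ((right && sd[a] == "+") || (left && sd[a] == "-")) {
      feature[a] <- "five_prime"
    } else {
      feature[a] <- "three_prime"
    }
  }
  mc$feature <- feature
  mc$element_id <- element_id
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Pairs of 5' and 3' LTR copy ids per complete provirus
#'
#' @param annotation GRanges with `feature` and `element_id` assigned (and
#'   a `copy_id` column; one is synthesised from coordinates if missing).
#' @return data.frame: element_id, five_prime, three_prime — one row per
#'   element having both LTRs; incomplete elements are skipped.
#' @export
elementLtrPairs <- function(annotation) {
  mc <- S4Vectors::mcols(annotation)
  if (!"copy_id" %in% names(mc))
    mc$copy_id <- paste0(GenomicRanges::seqnames(annotation), ":",
                         GenomicRanges::start(annotation))
  ok <- !is.na(mc$element_id) &
    (!("class" %in% names(mc)) | mc$class == "ltr") &
    mc$feature %in% c("five_prime", "three_prime")
  d <- data.frame(element_id = mc$element_id[ok], feature = mc$feature[ok],
                  copy_id = mc$copy_id[ok], stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    return(data.frame(element_id = character(), five_prime = character(),
                      three_prime = character(), stringsAsFactors = FALSE))
  five <- d[d$feature == "five_prime", ]
  three <- d[d$feature == "three_prime", ]
  ids <- intersect(five$element_id, three$element_id)
  data.frame(element_id = ids,
             five_prime = five$copy_id[match(ids, five$element_id)],
             three_prime = three$copy_id[match(ids, three$element_id)],
             stringsAsFactors = FALSE)
}

## coerce annotation data.frames (native or UCSC RepeatMasker columns) to
## GRanges; GRanges pass through
asRepeatGRanges <- function(x) {
  if (is(x, "GRanges")) return(x)
  d <- as.data.frame(x)
  if ("genoName" %in% names(d)) {
    d$chrom <- d$genoName; d$start <- d$genoStart + 1L; d$end <- d$genoEnd
    d$subfamily <- d$repName
    if (!"strand" %in% names(d)) d$strand <- "*"
  }
  need <- c("chrom", "start", "end", "strand", "subfamily")
  if (!all(need %in% names(d)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  extra <- setdiff(names(d), c("chrom", "start", "end", "strand", "width",
                               "genoName", "genoStart", "genoEnd", "repName"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(d[, extra, drop = FALSE])
  if (!"copy_id" %in% extra)
    S4Vectors::mcols(gr)$copy_id <- paste0(d$chrom, ":", d$start)
  gr
}
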