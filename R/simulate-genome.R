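## Planted primer-site preimages (unconverted top strand, element
## orientation).  After full bisulfite conversion of non-CpG cytosines the
## BS2 site on the sense strand reads exactly as the IAP-BS2 primer, and the
## BS1 site on the antisense strand reads as IAP-BS1 (with W = A).  Both
## preimages are CpG-free so primer annealing is independent of the
## methylation state.
BS1_PREIMAGE <- "CTTATGCTCTACCTTCCCC"            # revcomp+convert -> IAP-BS1
BS2_PREIMAGE <- "GGTCTTTGAAGATGTAAGTAATAAAGTCTT"  # convert -> IAP-BS2

## synthetic motif consensus strings planted in the hypomethylated clade
MAZ_SYN_CONSENSUS <- "GGGAGGGG"
UBP1_SYN_CONSENSUS <- "CTGGTTACAT"

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

countCpG <- function(seq) {
  length(Biostrings::matchPattern("CG", Biostrings::DNAString(seq)))
}

#' Built-in LTR subfamily consensus sequences
#'
#' Deterministically generated consensus sequences for four IAP-like LTR
#' subfamilies (IAPLTR1, IAPLTR2, IAPLTR2a2, IAPEY) plus an internal
#' ("IAP-int") consensus used as the body of full-length proviruses.  Each
#' LTR consensus is 300-450 bp, carries 15-25 CpG sites, contains the
#' IAP-BS1 and IAP-BS2 primer-site preimages in fixed windows, and is
#' subdivided into U3 / R / U5 regions.  For subfamilies that host a
#' hypomethylated clade, a clade profile (diagnostic substitutions plus
#' planted Maz-like and Ubp1-like motif instances and extra CpG sites in the
#' R region) is stored in `metadata()`.
#'
#' These sequences are synthetic stand-ins generated in code; they are not
#' the RepBase consensus sequences.
#'
#' @return A [Biostrings::DNAStringSet] named by subfamily with `mcols`
#'   columns `is_ltr`, `bs1_off`, `bs2_off`, `u3_end`, `r_end` and metadata
#'   entries `clade_edits` (per-subfamily data.frame of position/base
#'   substitutions), `motif_spans` (per-subfamily protected intervals) and
#'   `motif_consensus`.
#' @examples
#' cons <- defaultConsensi()
#' names(cons)
#' @export
defaultConsensi <- function() {
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(20170105L)

  spec <- data.frame(
    name = c("IAPLTR1", "IAPLTR2", "IAPLTR2a2", "IAPEY"),
    len = c(340L, 330L, 345L, 320L),
    stringsAsFactors = FALSE
  )
  seqs <- character(nrow(spec))
  bs1_off <- bs2_off <- u3_end <- r_end <- integer(nrow(spec))
  clade_edits <- list()
  motif_spans <- list()

  for (i in seq_len(nrow(spec))) {
    L <- spec$len[i]
    ## BS1 sits in U3 priming towards the 5' end and upstream flank; BS2
    ## sits in U5 priming towards the 3' end and downstream flank; the R
    ## region (between them) hosts the clade motif profile
    b1 <- as.integer(floor(0.38 * L))
    b2 <- as.integer(floor(0.82 * L))
    u3 <- as.integer(floor(0.55 * L))
    rr <- as.integer(floor(0.80 * L))
    repeat {
      s <- strsplit(randomDna(L), "")[[1]]
      s[b1:(b1 + 18L)] <- strsplit(BS1_PREIMAGE, "")[[1]]
      s[b1 + 19L] <- "A"                      # keep BS1 site CpG-free at its edge
      s[b2:(b2 + 29L)] <- strsplit(BS2_PREIMAGE, "")[[1]]
      seq <- paste(s, collapse = "")
      ncpg <- countCpG(seq)
      if (ncpg >= 15L && ncpg <= 25L) break
    }
    seqs[i] <- seq
    bs1_off[i] <- b1; bs2_off[i] <- b2; u3_end[i] <- u3; r_end[i] <- rr

    ## clade profile: planted in the R region (u3+1 .. rr)
    r0 <- u3 + 1L
    maz <- strsplit(MAZ_SYN_CONSENSUS, "")[[1]]
    ubp <- strsplit(UBP1_SYN_CONSENSUS, "")[[1]]
    plant <- rbind(
      data.frame(pos = r0 + 4L + seq_along(maz) - 1L, base = maz),
      data.frame(pos = r0 + 19L + seq_along(ubp) - 1L, base = ubp),
      data.frame(pos = r0 + 39L + seq_along(maz) - 1L, base = maz),
      ## extra CpG sites adjacent to the motifs (hypomethylated copies are
      ## CpG-richer around TF motifs)
      data.frame(pos = r0 + c(15L, 16L, 32L, 33L, 49L, 50L),
                 base = c("C", "G", "C", "G", "C", "G"))
    )
    ## diagnostic substitutions in U3, away from the BS1 site
    cand <- setdiff(40L:(u3 - 10L), b1:(b1 + 19L))
    diag_pos <- sort(sample(cand, 12L))
    svec <- strsplit(seq, "")[[1]]
    diag_base <- vapply(diag_pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), svec[p]), 1L)
    }, character(1))
    clade_edits[[spec$name[i]]] <- rbind(plant,
      data.frame(pos = diag_pos, base = diag_base))
    motif_spans[[spec$name[i]]] <- range(plant$pos)
  }

  ## internal consensus for full-length proviruses
  int_seq <- randomDna(1800L)
  cons <- Biostrings::DNAStringSet(c(seqs, int_seq))
  names(cons) <- c(spec$name, "IAP-int")
  S4Vectors::mcols(cons) <- S4Vectors::DataFrame(
    is_ltr = c(rep(TRUE, nrow(spec)), FALSE),
    bs1_off = c(bs1_off, NA), bs2_off = c(bs2_off, NA),
    u3_end = c(u3_end, NA), r_end = c(r_end, NA)
  )
  S4Vectors::metadata(cons) <- list(
    clade_edits = clade_edits,
    motif_spans = motif_spans,
    motif_consensus = c(Maz_syn = MAZ_SYN_CONSENSUS, Ubp1_syn = UBP1_SYN_CONSENSUS)
  )
  cons
}

applyEdits <- function(chars, edits) {
  if (nrow(edits)) chars[edits$pos] <- edits$base
  chars
}

mutateCopy <- function(chars, rate, protect = integer()) {
  n <- length(chars)
  k <- stats::rbinom(1, n, rate)
  if (k == 0L) return(list(chars = chars, pos = integer()))
  cand <- setdiff(seq_len(n), protect)
  pos <- sort(sample(cand, min(k, length(cand))))
  chars[pos] <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L), character(1))
  list(chars = chars, pos = pos)
}

#' Build a synthetic repeat-bearing genome
#'
#' Plants solo LTRs and full-length proviruses (5' LTR - internal - 3' LTR,
#' contiguous on one strand) of the configured subfamilies into unique
#' random flanks, applies per-copy substitutions against the consensus, and
#' applies the clade profile (diagnostic substitutions + motif instances) to
#' the copies designated hypomethylated.  Loci are concatenated on three
#' chromosomes in shuffled order.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param consensi Subfamily consensus set as from [defaultConsensi()].
#' @return List with `genome` (named [Biostrings::DNAStringSet]) and
#'   `annotation` (a [GenomicRanges::GRanges], 1-based, with mcols
#'   `copy_id`, `subfamily`, `class` ("ltr"/"internal"), `feature`
#'   ("five_prime"/"three_prime"/"solo"), `element_id`, `clade`
#'   ("hyper"/"hypo"), `hypo_tissues` (comma-separated), `n_mut`).
#' @examples
#' cfg <- simConfig(seed = 7L, copy_plan = data.frame(
#'   subfamily = "IAPLTR1", n_solo = 2L, n_full = 1L, n_hypo = 0L,
#'   hypo_tissue = NA))
#' sim <- buildGenome(cfg)
#' sim$annotation
#' @export
buildGenome <- function(config, consensi = defaultConsensi()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  mc <- S4Vectors::mcols(consensi)
  if (anyDuplicated(names(consensi))) stop("consensus names must be unique")
  for (nm in names(consensi)[mc$is_ltr]) {
    i <- match(nm, names(consensi))
    L <- S4Vectors::width(consensi)[i]
    if (mc$bs2_off[i] + nchar(BS2_PREIMAGE) - 1L > L || mc$bs1_off[i] + 18L > L)
      stop("consensus '", nm, "' too short for the primer sites")
  }
  plan <- config@copy_plan
  miss <- setdiff(plan$subfamily, names(consensi)[mc$is_ltr])
  if (length(miss)) stop("no consensus for subfamily: ", paste(miss, collapse = ", "))
  if (!"IAP-int" %in% names(consensi)) stop("internal consensus 'IAP-int' required")

  set.seed(deriveSeed(config@seed, "genome"))
  int_chars <- strsplit(as.character(consensi[["IAP-int"]]), "")[[1]]
  clade_edits <- S4Vectors::metadata(consensi)$clade_edits
  motif_spans <- S4Vectors::metadata(consensi)$motif_spans

  loci <- list()   # each: list(seq, rows = data.frame of parts)
  for (i in seq_len(nrow(plan))) {
    sf <- plan$subfamily[i]
    ci <- match(sf, names(consensi))
    cons_chars <- strsplit(as.character(consensi[[sf]]), "")[[1]]
    Lc <- length(cons_chars)
    hypo_idx <- sort(sample(seq_len(plan$n_solo[i]), plan$n_hypo[i]))
    edits <- clade_edits[[sf]]
    protect <- if (!is.null(edits)) edits$pos else integer()

    for (j in seq_len(plan$n_solo[i])) {
      hypo <- j %in% hypo_idx
      chars <- cons_chars
      if (hypo) chars <- applyEdits(chars, edits)
      m <- mutateCopy(chars, config@mutation_rate,
                      protect = if (hypo) protect else integer())
      strand <- sample(c("+", "-"), 1)
      copy_id <- sprintf("%s_s%02d", sf, j)
      loci[[length(loci) + 1L]] <- list(
        parts = list(list(chars = m$chars, class = "ltr", feature = "solo",
                          copy_id = copy_id, subfamily = sf,
                          element_id = NA_character_,
                          clade = if (hypo) "hypo" else "hyper",
                          hypo_tissue = if (hypo) plan$hypo_tissue[i] else NA_character_,
                          n_mut = length(m$pos))),
        strand = strand)
    }
    for (j in seq_len(plan$n_full[i])) {
      eid <- sprintf("%s_f%02d", sf, j)
      m5 <- mutateCopy(cons_chars, config@mutation_rate)
      mi <- mutateCopy(int_chars, config@mutation_rate)
      m3 <- mutateCopy(cons_chars, config@mutation_rate)
      strand <- sample(c("+", "-"), 1)
      mk <- function(m, class, feature, suffix, sfam) {
        list(chars = m$chars, class = class, feature = feature,
             copy_id = paste0(eid, suffix), subfamily = sfam,
             element_id = eid, clade = "hyper", hypo_tissue = NA_character_,
             n_mut = length(m$pos))
      }
      loci[[length(loci) + 1L]] <- list(
        parts = list(mk(m5, "ltr", "five_prime", "_5p", sf),
                     mk(mi, "internal", NA_character_, "_int", "IAP-int"),
                     mk(m3, "ltr", "three_prime", "_3p", sf)),
        strand = strand)
    }
  }

  ## copies hypomethylated in every tissue
  all_hypo <- which(vapply(loci, function(l)
    identical(l$parts[[1]]$clade, "hypo"), logical(1)))
  if (config@n_hypo_both > 0L && length(all_hypo)) {
    both <- sample(all_hypo, min(config@n_hypo_both, length(all_hypo)))
    for (b in both) loci[[b]]$parts[[1]]$hypo_tissue <- paste(config@tissues, collapse = ",")
  }

  ## shuffle and lay out on three chromosomes
  loci <- loci[sample(length(loci))]
  nchrom <- 3L
  chrom_of <- rep_len(seq_len(nchrom), length(loci))
  chrom_seq <- vector("list", nchrom)
  rows <- list()
  offs <- integer(nchrom)
  fl <- config@flank_length
  for (k in seq_along(loci)) {
    l <- loci[[k]]
    ch <- chrom_of[k]
    ## element in genome orientation
    part_chars <- lapply(l$parts, `[[`, "chars")
    if (l$strand == "-") {
      part_chars <- rev(lapply(part_chars, function(p)
        rev(chartr("ACGT", "TGCA", p))))
      part_meta <- rev(l$parts)
    } else part_meta <- l$parts
    flank_l <- strsplit(randomDna(fl), "")[[1]]
    flank_r <- strsplit(randomDna(fl), "")[[1]]
    pos <- offs[ch] + fl
    for (p in seq_along(part_chars)) {
      w <- length(part_chars[[p]])
      meta <- part_meta[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste0("chr", ch), start = pos + 1L, end = pos + w,
        strand = l$strand, copy_id = meta$copy_id, subfamily = meta$subfamily,
        class = meta$class, feature = meta$feature, element_id = meta$element_id,
        clade = meta$clade, hypo_tissues = meta$hypo_tissue, n_mut = meta$n_mut,
        stringsAsFactors = FALSE)
      pos <- pos + w
    }
    chrom_seq[[ch]] <- c(chrom_seq[[ch]], list(flank_l), part_chars, list(flank_r))
    offs[ch] <- pos + fl
  }
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, function(x)
    paste(unlist(x), collapse = ""), character(1)))
  names(genome) <- paste0("chr", seq_len(nchrom))

  ann <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start, ann$end),
                               strand = ann$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ann[, c("copy_id", "subfamily", "class", "feature", "element_id",
            "clade", "hypo_tissues", "n_mut")])
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!all(S4Vectors::width(genome)[match(as.character(GenomicRanges::seqnames(gr)),
                                          names(genome))] >= GenomicRanges::end(gr)))
    stop("internal error: planted copy exceeds chromosome bounds")
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, ignore.strand = TRUE)
  if (length(ov)) stop("planted copies overlap")

  list(genome = genome, annotation = gr, consensi = consensi)
}

#' Locate the primer-site coordinates of an LTR copy
#'
#' Returns top-strand 1-based intervals of the BS1 and BS2 primer-site
#' preimages within a planted copy, together with the template strand each
#' primer anneals to and the direction the amplicon extends.
#' @keywords internal
primerSites <- function(start, end, strand, bs1_off, bs2_off) {
  w1 <- nchar(BS1_PREIMAGE); w2 <- nchar(BS2_PREIMAGE)
  topIv <- function(off, w) {
    if (strand == "+") c(start + off - 1L, start + off + w - 2L)
    else c(end - off - w + 2L, end - off + 1L)
  }
  b1 <- topIv(bs1_off, w1); b2 <- topIv(bs2_off, w2)
  ## BS2 template is the copy's sense strand; BS1 the antisense strand.
  bs2_template <- if (strand == "+") "top" else "bottom"
  bs1_template <- if (strand == "+") "bottom" else "top"
  list(bs1 = list(iv = b1, template = bs1_template),
       bs2 = list(iv = b2, template = bs2_template))
}
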