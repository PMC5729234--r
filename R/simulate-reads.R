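## complement for character vectors
compChars <- function(x) chartr("ACGT", "TGCA", x)

#' Simulate TEPBAT paired-end reads
#'
#' Per molecule: a library side (BS1 or BS2, i.e. which genomic strand
#' serves as the bisulfite-converted template) is chosen at random; the
#' template is converted (CpG cytosines stay C with their truth
#' probability, all other cytosines convert with `conversion_rate`); the
#' IAP primer must match the converted template at its designed site with
#' at most `max_primer_mismatch` IUPAC-aware mismatches or the molecule is
#' dropped; the random-primed end is placed so the fragment length is
#' uniform on `fragment_range`.  Read 2 starts with the incorporated IAP
#' primer; read 1 starts with the 19-nt tag followed by the 4 genomic bases
#' matched by the random tetramer.
#'
#' @param sim Output of [buildGenome()].
#' @param truth A `TruthMethylome` from [assignMethylome()].
#' @param config A \linkS4class{SimConfig}.
#' @param primers Primer list as [tepbatPrimers()].
#' @param max_primer_mismatch Retention tolerance at the primer site.
#' @return List of class `TepbatReads` with `reads` (data.frame: read_id,
#'   tissue, read1, qual1, read2, qual2) and `truth` (read_id, tissue,
#'   copy_id, side, template, chrom, frag_start, frag_end, anchor_start,
#'   anchor_end; anchor coordinates are the genomic span of read 1 after
#'   tag + tetramer removal, 1-based top strand).  Copies whose primer site
#'   is no longer matchable yield zero reads with a warning.
#' @export
simulateTepbatReads <- function(sim, truth, config,
                                primers = tepbatPrimers(),
                                max_primer_mismatch = 2L) {
  stopifnot(is(config, "SimConfig"))
  assertIupac(unlist(primers))
  annotation <- sim$annotation
  genome <- sim$genome
  ltr <- annotation[S4Vectors::mcols(annotation)$class == "ltr"]
  mc <- S4Vectors::mcols(ltr)
  cons <- sim$consensi
  cm <- S4Vectors::mcols(cons)

  set.seed(deriveSeed(config@seed, "reads"))
  chrom_chars <- lapply(genome, function(s) strsplit(as.character(s), "")[[1]])
  chrom_len <- vapply(chrom_chars, length, integer(1))

  ## truth lookup: per tissue+chrom an env pos -> prob
  site_map <- list()
  for (t in config@tissues) {
    s <- truth$sites[truth$sites$tissue == t, ]
    site_map[[t]] <- lapply(split(s, s$chrom), function(d) {
      v <- d$prob; names(v) <- d$pos; v
    })
  }
  lookupProb <- function(tissue, chrom, pos) {
    m <- site_map[[tissue]][[chrom]]
    if (is.null(m)) return(rep(config@flank_meth_level, length(pos)))
    p <- unname(m[as.character(pos)])
    p[is.na(p)] <- config@flank_meth_level
    p
  }

  tag <- primers$tag
  rl <- config@read_length
  fr <- config@fragment_range
  frag_lens <- fr[1]:fr[2]
  gen_len1 <- rl - nchar(tag)                 # genomic bases in read 1 (incl tetramer)

  reads <- list(); truths <- list()
  dropped_primer <- 0L
  silent_copies <- character()

  for (ti in seq_along(config@tissues)) {
    tissue <- config@tissues[ti]
    for (i in seq_along(ltr)) {
      copy_id <- mc$copy_id[i]
      sf <- mc$subfamily[i]
      ci <- match(sf, names(cons))
      ps <- primerSites(GenomicRanges::start(ltr)[i], GenomicRanges::end(ltr)[i],
                        as.character(GenomicRanges::strand(ltr))[i],
                        cm$bs1_off[ci], cm$bs2_off[ci])
      chrom <- as.character(GenomicRanges::seqnames(ltr))[i]
      gch <- chrom_chars[[chrom]]
      n_emitted <- 0L
      for (j in seq_len(config@molecules_per_copy)) {
        side <- sample(c("bs1", "bs2"), 1L)
        primer <- primers[[if (side == "bs1") "bs1" else "bs2"]]
        np <- nchar(primer)
        site <- ps[[side]]
        Lf <- sample(frag_lens, 1L)
        if (site$template == "top") {
          fs <- site$iv[1]; fe <- fs + Lf - 1L
          if (fe > chrom_len[chrom]) next
          v <- gch[fs:fe]
          ## convert top strand
          cidx <- which(v == "C")
          if (length(cidx)) {
            abs <- fs + cidx - 1L
            is_cpg <- abs < chrom_len[chrom] & gch[pmin(abs + 1L, chrom_len[chrom])] == "G"
            keep <- logical(length(cidx))
            if (any(is_cpg))
              keep[is_cpg] <- stats::runif(sum(is_cpg)) <
                lookupProb(tissue, chrom, abs[is_cpg])
            if (any(!is_cpg))
              keep[!is_cpg] <- stats::runif(sum(!is_cpg)) >= config@conversion_rate
            v[cidx[!keep]] <- "T"
          }
          A <- v
          ## read 1 is the reverse complement of the far fragment end; the
          ## tetramer occupies the 4 outermost bases (top positions fe-3..fe)
          anchor_hi <- fe; anchor_lo <- fe - gen_len1 + 1L
          anchor_start <- anchor_lo
          anchor_end <- anchor_hi - TAG_TETRAMER
          template_strand <- "+"
        } else {
          fe <- site$iv[2]; fs <- fe - Lf + 1L
          if (fs < 1L) next
          v <- gch[fs:fe]
          w <- compChars(v)                   # bottom strand, still left-to-right
          gidx <- which(v == "G")             # bottom-strand cytosines
          if (length(gidx)) {
            abs <- fs + gidx - 1L
            is_cpg <- abs > 1L & gch[pmax(abs - 1L, 1L)] == "C"
            keep <- logical(length(gidx))
            if (any(is_cpg))
              keep[is_cpg] <- stats::runif(sum(is_cpg)) <
                lookupProb(tissue, chrom, abs[is_cpg] - 1L)
            if (any(!is_cpg))
              keep[!is_cpg] <- stats::runif(sum(!is_cpg)) >= config@conversion_rate
            w[gidx[!keep]] <- "T"
          }
          A <- rev(w)                         # template 5'->3'
          anchor_lo <- fs; anchor_hi <- fs + gen_len1 - 1L
          anchor_start <- anchor_lo + TAG_TETRAMER
          anchor_end <- anchor_hi
          template_strand <- "-"
        }
        ## primer must still match the converted template
        tmpl_site <- paste(A[1:np], collapse = "")
        mm <- primerMismatches(primer, tmpl_site)
        if (is.na(mm) || mm > max_primer_mismatch) {
          dropped_primer <- dropped_primer + 1L
          next
        }
        ## incorporate the primer (realise IUPAC positions from the template
        ## when compatible)
        pv <- strsplit(primer, "")[[1]]
        amb <- !pv %in% c("A", "C", "G", "T")
        if (any(amb)) {
          tv <- A[seq_len(np)][amb]
          ok <- iupacBaseMatch(pv[amb], tv)
          pv[amb][ok] <- tv[ok]
          if (any(!ok)) pv[amb][!ok] <- vapply(pv[amb][!ok], function(code)
            sample(strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]], 1L),
            character(1))
        }
        A[seq_len(np)] <- pv
        rc <- rev(compChars(A))
        read2 <- paste(A[seq_len(rl)], collapse = "")
        read1 <- paste0(tag, paste(rc[seq_len(gen_len1)], collapse = ""))
        if (config@seq_error_rate > 0) {
          read1 <- addSeqErrors(read1, config@seq_error_rate)
          read2 <- addSeqErrors(read2, config@seq_error_rate)
        }
        n_emitted <- n_emitted + 1L
        rid <- sprintf("%s_%s_m%04d", tissue, copy_id, j)
        reads[[length(reads) + 1L]] <- data.frame(
          read_id = rid, tissue = tissue, read1 = read1,
          qual1 = strrep(rawToChar(as.raw(config@base_quality + 33L)), rl),
          read2 = read2,
          qual2 = strrep(rawToChar(as.raw(config@base_quality + 33L)), rl),
          stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- data.frame(
          read_id = rid, tissue = tissue, copy_id = copy_id, side = side,
          template = template_strand, chrom = chrom,
          frag_start = fs, frag_end = fe,
          anchor_start = anchor_start, anchor_end = anchor_end,
          stringsAsFactors = FALSE)
      }
      if (n_emitted == 0L && ti == 1L)
        silent_copies <- c(silent_copies, copy_id)
    }
  }
  if (length(silent_copies))
    warning("copies yielded zero reads (primer site not matchable): ",
            paste(silent_copies, collapse = ", "))
  out <- list(reads = do.call(rbind, reads), truth = do.call(rbind, truths),
              dropped_primer = dropped_primer)
  class(out) <- c("TepbatReads", "list")
  out
}

addSeqErrors <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- vapply(hit, function(p)
      sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L), character(1))
  paste(v, collapse = "")
}

#' @export
print.TepbatReads <- function(x, ...) {
  cat("TepbatReads:", nrow(x$reads), "read pairs (",
      x$dropped_primer, "molecules dropped at the primer check )\n")
  invisible(x)
}

#' Write simulated reads as paired FASTQ (Phred+33)
#'
#' @param reads A `TepbatReads` object or its `reads` data.frame.
#' @param dir Output directory.
#' @param prefix File prefix; files are `<prefix>_<tissue>_R1.fastq` / `_R2.fastq`.
#' @return Invisible character vector of file paths.
#' @export
writeTepbatFastq <- function(reads, dir, prefix = "tepbat") {
  if (is.list(reads) && !is.data.frame(reads)) reads <- reads$reads
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (t in unique(reads$tissue)) {
    d <- reads[reads$tissue == t, ]
    for (mate in 1:2) {
      f <- file.path(dir, sprintf("%s_%s_R%d.fastq", prefix, t, mate))
      sq <- if (mate == 1) d$read1 else d$read2
      ql <- if (mate == 1) d$qual1 else d$qual2
      writeLines(as.vector(rbind(paste0("@", d$read_id, "/", mate), sq, "+", ql)), f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Read paired FASTQ into the internal read-pair table
#'
#' @param r1,r2 FASTQ paths for mates 1 and 2.
#' @param tissue Tissue label to attach.
#' @return data.frame like the `reads` element of [simulateTepbatReads()].
#' @export
readTepbatFastq <- function(r1, r2, tissue = NA_character_) {
  parse1 <- function(f) {
    x <- readLines(f)
    if (length(x) %% 4L != 0L) stop("malformed FASTQ: ", f)
    list(id = sub("^@", "", sub("/[12]$", "", x[seq(1, length(x), 4)])),
         seq = x[seq(2, length(x), 4)], qual = x[seq(4, length(x), 4)])
  }
  a <- parse1(r1); b <- parse1(r2)
  if (!identical(a$id, b$id)) stop("mate files are not in the same order")
  data.frame(read_id = a$id, tissue = tissue, read1 = a$seq, qual1 = a$qual,
             read2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
}
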