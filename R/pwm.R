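PWM_BIN_BITS <- 0.001  # score discretisation: 1/1000 bit bins
PWM_SCORE_FLOOR <- -20 # bits; zero-probability cells are floored here so
                       # the discretised null stays finite (the floor is
                       # far below any reportable score)

## integer-discretised log-likelihood-ratio scores, 4 x L
pwmIntScores <- function(motif) {
  lr <- log2(motif@matrix / motif@background)
  lr[lr < PWM_SCORE_FLOOR] <- PWM_SCORE_FLOOR
  round(lr / PWM_BIN_BITS)
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programming over integer-discretised scores: the null is a
#' random word drawn from the 0-order background, and the survival
#' function P(score >= s) is exact on the discretised grid.
#'
#' @param motif A \linkS4class{MotifModel}.
#' @return List: `support` (integer scores), `prob`, `survival`
#'   (P(S >= support)).
#' @export
pwmScoreDistribution <- function(motif) {
  S <- pwmIntScores(motif)
  bg <- motif@background
  L <- ncol(S)
  p_cur <- numeric(max(S[, 1]) - min(S[, 1]) + 1L)
  base <- min(S[, 1])
  for (b in 1:4) p_cur[S[b, 1] - base + 1L] <- p_cur[S[b, 1] - base + 1L] + bg[b]
  cur_lo <- base
  if (L > 1L) for (i in 2:L) {
    ci <- S[, i]
    nb <- min(ci); xb <- max(ci)
    new <- numeric(length(p_cur) + xb - nb)
    for (b in 1:4) {
      sh <- ci[b] - nb
      idx <- seq_along(p_cur) + sh
      new[idx] <- new[idx] + p_cur * bg[b]
    }
    p_cur <- new
    cur_lo <- cur_lo + nb
  }
  support <- cur_lo + seq_along(p_cur) - 1L
  surv <- rev(cumsum(rev(p_cur)))
  list(support = support, prob = p_cur, survival = surv)
}

## p-value of an integer score under the exact null
pwmPValue <- function(dist, int_score) {
  idx <- int_score - dist$support[1] + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$survival) + 1L)
  ifelse(idx > length(dist$survival), 0, dist$survival[idx])
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2 likelihood-ratio score against the motif background at every
#' offset on both strands; per-hit p-values from the exact discretised
#' null ([pwmScoreDistribution()]); hits with p below the motif's
#' threshold are reported.
#'
#' @param sequence Character scalar or [Biostrings::DNAString].
#' @param motif A \linkS4class{MotifModel}.
#' @param both_strands Scan the reverse complement too.
#' @return data.frame: start, end (1-based on the input sequence), strand,
#'   score (bits), p_value.  Empty when the motif is longer than the
#'   sequence.
#' @export
scanPwm <- function(sequence, motif, both_strands = TRUE) {
  sequence <- toupper(as.character(sequence))
  L <- motifLength(motif)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  if (n < L) return(empty)
  dist <- pwmScoreDistribution(motif)
  S <- pwmIntScores(motif)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (sd in strands) {
    s <- if (sd == "+") sequence else revComp(sequence)
    enc <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    no <- n - L + 1L
    sc <- numeric(no); valid <- rep(TRUE, no)
    for (i in seq_len(L)) {
      b <- enc[seq_len(no) + i - 1L]
      valid <- valid & !is.na(b)
      contrib <- S[cbind(ifelse(is.na(b), 1L, b), i)]
      sc <- sc + contrib
    }
    pv <- pwmPValue(dist, as.integer(round(sc)))
    hit <- valid & pv < motif@pvalue_threshold
    if (any(hit)) {
      ## map reverse-strand offsets back to input coordinates
      st <- if (sd == "+") which(hit) else n - L + 2L - which(hit)
      out[[length(out) + 1L]] <- data.frame(
        start = st, end = st + L - 1L, strand = sd,
        score = sc[hit] * PWM_BIN_BITS,
        p_value = pv[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Clade-specific motif enrichment
#'
#' Per motif: presence (>= 1 scan hit) per sequence, a two-sided Fisher
#' exact test of presence across the two clades, and BH-corrected
#' q-values across the motif set.  Per-sequence hit counts are attached
#' as attribute `hit_counts`.
#'
#' @param clades Named list of two sequence sets (character vectors or
#'   DNAStringSets), e.g. `list(hypo = ..., hyper = ...)`; the first is
#'   treated as the hypomethylated clade.
#' @param motifs List of \linkS4class{MotifModel}s.
#' @param estimate_background Re-estimate the 0-order background from the
#'   scanned sequences (default TRUE).
#' @return data.frame: motif, present_hypo, n_hypo, present_hyper,
#'   n_hyper, odds_ratio, p_value, q_value, ordered by q then p.
#' @export
cladeMotifEnrichment <- function(clades, motifs, estimate_background = TRUE) {
  if (length(clades) != 2L) stop("exactly two clades required")
  if (any(vapply(clades, length, integer(1)) == 0L)) stop("empty clade")
  toChar <- function(x) if (is(x, "XStringSet")) as.character(x) else x
  clades <- lapply(clades, toChar)
  if (estimate_background) {
    pooled <- paste(unlist(clades), collapse = "")
    cnt <- table(factor(strsplit(pooled, "")[[1]], levels = c("A", "C", "G", "T")))
    bg <- as.numeric(cnt) / sum(cnt)
    motifs <- lapply(motifs, function(m)
      motifModel(m@name, m@matrix, background = bg, pseudocount = 0,
                 pvalue_threshold = m@pvalue_threshold))
  }
  hit_counts <- list()
  rows <- list()
  for (m in motifs) {
    nh <- lapply(clades, function(ss)
      vapply(ss, function(s) nrow(scanPwm(s, m)), integer(1)))
    hit_counts[[motifName(m)]] <- nh
    a <- sum(nh[[1]] > 0L); b <- length(nh[[1]]) - a
    cc <- sum(nh[[2]] > 0L); d <- length(nh[[2]]) - cc
    er <- featureEnrichment(counts = c(a, b, cc, d), feature = motifName(m))
    rows[[length(rows) + 1L]] <- data.frame(
      motif = motifName(m), present_hypo = a, n_hypo = a + b,
      present_hyper = cc, n_hyper = cc + d,
      odds_ratio = er$odds_ratio, p_value = er$p_value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "hit_counts") <- hit_counts
  res
}

#' CpG density by clade, overall and around motif hits
#'
#' Counts CpG dinucleotides per sequence (position-based, so "CGCG"
#' counts 2) overall and within +/- `window` bp of motif scan hits, and
#' compares the clades with a rank-sum test.
#'
#' @param clades Named list of two sequence sets (first = hypomethylated).
#' @param motifs List of \linkS4class{MotifModel}s used to define hit
#'   windows (optional; without motifs only overall counts are returned).
#' @param window Half-width (bp) of the window around each hit.
#' @return List: `per_sequence` (clade, seq, cpg_total, cpg_near_motif),
#'   `p_overall`, `p_near_motif` (Wilcoxon rank-sum).
#' @export
cpgDensityByClade <- function(clades, motifs = NULL, window = 50L) {
  if (length(clades) != 2L) stop("exactly two clades required")
  toChar <- function(x) if (is(x, "XStringSet")) as.character(x) else x
  clades <- lapply(clades, toChar)
  rows <- list()
  for (cl in names(clades)) {
    for (nm in seq_along(clades[[cl]])) {
      s <- clades[[cl]][nm]
      cpg_pos <- Biostrings::start(
        Biostrings::matchPattern("CG", Biostrings::DNAString(unname(s))))
      near <- NA_integer_
      if (!is.null(motifs)) {
        hits <- do.call(rbind, lapply(motifs, function(m) scanPwm(s, m)))
        if (!is.null(hits) && nrow(hits)) {
          inwin <- rep(FALSE, length(cpg_pos))
          for (h in seq_len(nrow(hits)))
            inwin <- inwin | (cpg_pos >= hits$start[h] - window &
                              cpg_pos <= hits$end[h] + window)
          near <- sum(inwin)
        } else near <- 0L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, seq = if (!is.null(names(s))) names(s) else as.character(nm),
        cpg_total = length(cpg_pos), cpg_near_motif = near,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  cl1 <- d$clade == names(clades)[1]
  p_overall <- tryCatch(
    stats::wilcox.test(d$cpg_total[cl1], d$cpg_total[!cl1], exact = FALSE)$p.value,
    error = function(e) NA_real_)
  p_near <- if (!is.null(motifs)) tryCatch(
    stats::wilcox.test(d$cpg_near_motif[cl1], d$cpg_near_motif[!cl1],
                       exact = FALSE)$p.value,
    error = function(e) NA_real_) else NA_real_
  list(per_sequence = d, p_overall = p_overall, p_near_motif = p_near)
}

#' Built-in synthetic TF motif models
#'
#' The Maz-like (G-rich) and Ubp1-like motif models whose consensus
#' strings are planted in the hypomethylated clade by the genome
#' generator.  They are synthetic PWMs built in code (0.85 on the
#' consensus base), not database matrices.
#'
#' @param pvalue_threshold Scan threshold.
#' @return Named list of \linkS4class{MotifModel}s.
#' @export
syntheticMotifs <- function(pvalue_threshold = 1e-4) {
  mk <- function(name, consensus) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix(0.05, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 0.85
    motifModel(name, m, pseudocount = 0, pvalue_threshold = pvalue_threshold)
  }
  list(Maz_syn = mk("Maz_syn", MAZ_SYN_CONSENSUS),
       Ubp1_syn = mk("Ubp1_syn", UBP1_SYN_CONSENSUS))
}

#' Read and write minimal MEME-format motif files
#'
#' Supports the text MEME v4 dialect: a background line and
#' letter-probability matrices over the ACGT alphabet.
#'
#' @param file Path.
#' @param pvalue_threshold Threshold attached to each loaded motif.
#' @return `readMemeMotifs` returns a named list of
#'   \linkS4class{MotifModel}s.
#' @export
readMemeMotifs <- function(file, pvalue_threshold = 1e-4) {
  x <- readLines(file)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", x)
  if (length(bgl) && bgl[1] < length(x)) {
    tok <- strsplit(trimws(x[bgl[1] + 1L]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    num <- v[!is.na(v)]
    if (length(num) == 4L) bg <- num
  }
  starts <- grep("^MOTIF\\b", x)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(x[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", x[s:length(x)])[1] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", x[h]))
    rows <- lapply(x[(h + 1L):(h + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    motifs[[name]] <- motifModel(name, m, background = bg, pseudocount = 0,
                                 pvalue_threshold = pvalue_threshold)
  }
  motifs
}

#' @rdname readMemeMotifs
#' @param motifs Named list of \linkS4class{MotifModel}s.
#' @export
writeMemeMotifs <- function(motifs, file) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", c("A", "C", "G", "T"),
                         motifs[[1]]@background), collapse = " "), "")
  for (m in motifs) {
    out <- c(out, paste("MOTIF", motifName(m)),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     motifLength(m)),
             apply(motifMatrix(m), 2, function(col)
               paste(sprintf("%.6f", col), collapse = " ")),
             "")
  }
  writeLines(out, file)
  invisible(file)
}
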