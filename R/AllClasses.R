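#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

#' Simulation configuration for a TEPBAT-style experiment
#'
#' Holds every knob of the synthetic-data generator: the copy plan (how many
#' solo LTRs, full-length proviruses and hypomethylated copies to plant per
#' subfamily, and in which tissue the hypomethylated clade is
#' hypomethylated), library geometry (fragment size range, read length),
#' bisulfite conversion rate, and the per-copy methylation-level
#' distributions.
#'
#' @section Slots:
#' \describe{
#'   \item{seed}{Integer master seed; every stage derives its own stream
#'     from it.}
#'   \item{copy_plan}{data.frame with columns `subfamily`, `n_solo`,
#'     `n_full` (proviruses), `n_hypo` (hypomethylated solo copies) and
#'     `hypo_tissue`.}
#'   \item{tissues}{Character vector of tissue labels (default sperm, tail).}
#'   \item{n_hypo_both}{How many of the planted hypomethylated copies are
#'     hypomethylated in every tissue rather than tissue-specifically.}
#'   \item{flank_length}{bp of unique random flank on each side of a locus.}
#'   \item{mutation_rate}{Per-base substitution rate of each copy relative
#'     to its subfamily consensus.}
#'   \item{conversion_rate}{Probability that an unmethylated cytosine reads
#'     as T after bisulfite conversion.}
#'   \item{fragment_range}{Two integers, min and max PCR fragment length.}
#'   \item{read_length}{Sequenced read length.}
#'   \item{molecules_per_copy}{Pre-PCR molecules drawn per copy and tissue.}
#'   \item{hyper_shape}{Beta shape parameters of the copy-level methylation
#'     mean for hypermethylated copies (default mean 0.9).}
#'   \item{hypo_max,hypo_shape}{Hypomethylated copy-level means are
#'     `hypo_max` times a Beta(`hypo_shape`) draw, so support is
#'     within [0, hypo_max].}
#'   \item{flank_meth_level}{Constant true methylation of flanking
#'     (non-repeat) CpG sites.}
#'   \item{cpg_jitter_sd}{Optional within-copy jitter of per-CpG truth
#'     around the copy mean (0 = exact copy mean, the default).}
#'   \item{seq_error_rate}{Optional uniform substitution error rate applied
#'     to read bases.}
#'   \item{base_quality}{Constant Phred quality of simulated bases.}
#' }
#'
#' @name SimConfig-class
#' @rdname SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer",
  copy_plan = "data.frame",
  tissues = "character",
  n_hypo_both = "integer",
  flank_length = "integer",
  mutation_rate = "numeric",
  conversion_rate = "numeric",
  fragment_range = "integer",
  read_length = "integer",
  molecules_per_copy = "integer",
  hyper_shape = "numeric",
  hypo_max = "numeric",
  hypo_shape = "numeric",
  flank_meth_level = "numeric",
  cpg_jitter_sd = "numeric",
  seq_error_rate = "numeric",
  base_quality = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cp <- object@copy_plan
  need <- c("subfamily", "n_solo", "n_full", "n_hypo", "hypo_tissue")
  if (!all(need %in% names(cp)))
    msg <- c(msg, paste("copy_plan must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cp$subfamily)) msg <- c(msg, "duplicate subfamily in copy_plan")
    if (any(cp$n_hypo > cp$n_solo))
      msg <- c(msg, "n_hypo cannot exceed n_solo (hypomethylated copies are planted as solo LTRs)")
    bad <- !is.na(cp$hypo_tissue) & !(cp$hypo_tissue %in% object@tissues)
    if (any(bad)) msg <- c(msg, "hypo_tissue not among tissues")
  }
  if (object@conversion_rate < 0 || object@conversion_rate > 1)
    msg <- c(msg, "conversion_rate must be in [0,1]")
  if (length(object@fragment_range) != 2L ||
      object@fragment_range[1] > object@fragment_range[2])
    msg <- c(msg, "fragment_range must be increasing [min, max]")
  if (object@read_length > object@fragment_range[1])
    msg <- c(msg, "read_length must not exceed the minimum fragment length")
  if (object@hypo_max <= 0 || object@hypo_max > 1)
    msg <- c(msg, "hypo_max must be in (0,1]")
  if (length(object@tissues) < 1L) msg <- c(msg, "at least one tissue required")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults encode the study conditions at desk scale: four targeted
#' subfamilies, a hypermethylated majority centred at 0.9, a hypomethylated
#' minority (levels within [0, 0.2]) planted as solo LTRs of specific
#' subfamilies in specific tissues (IAPLTR2a2 and IAPEY in sperm, IAPLTR2 in
#' tail, with 3 copies hypomethylated in both), 350-450 bp fragments and
#' paired 100-bp reads.
#'
#' @param seed Integer master seed.
#' @param copy_plan See \linkS4class{SimConfig}; default plants
#'   120 LTR copies across IAPLTR1/IAPLTR2/IAPLTR2a2/IAPEY.
#' @param tissues Tissue labels.
#' @param n_hypo_both Copies hypomethylated in all tissues.
#' @param flank_length,mutation_rate,conversion_rate,fragment_range
#'   Generator parameters, see class docs.
#' @param read_length,molecules_per_copy,hyper_shape,hypo_max,hypo_shape
#'   Generator parameters, see class docs.
#' @param flank_meth_level,cpg_jitter_sd,seq_error_rate,base_quality
#'   Generator parameters, see class docs.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1L)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      copy_plan = defaultCopyPlan(),
                      tissues = c("sperm", "tail"),
                      n_hypo_both = 3L,
                      flank_length = 600L,
                      mutation_rate = 0.02,
                      conversion_rate = 0.995,
                      fragment_range = c(350L, 450L),
                      read_length = 100L,
                      molecules_per_copy = 30L,
                      hyper_shape = c(27, 3),
                      hypo_max = 0.2,
                      hypo_shape = c(1.5, 6),
                      flank_meth_level = 0.75,
                      cpg_jitter_sd = 0,
                      seq_error_rate = 0,
                      base_quality = 37L) {
  new("SimConfig",
      seed = as.integer(seed), copy_plan = copy_plan,
      tissues = tissues, n_hypo_both = as.integer(n_hypo_both),
      flank_length = as.integer(flank_length),
      mutation_rate = mutation_rate, conversion_rate = conversion_rate,
      fragment_range = as.integer(fragment_range),
      read_length = as.integer(read_length),
      molecules_per_copy = as.integer(molecules_per_copy),
      hyper_shape = hyper_shape, hypo_max = hypo_max,
      hypo_shape = hypo_shape, flank_meth_level = flank_meth_level,
      cpg_jitter_sd = cpg_jitter_sd, seq_error_rate = seq_error_rate,
      base_quality = as.integer(base_quality))
}

#' Default copy plan
#'
#' 120 LTR copies: IAPLTR1 (8 solo + 6 proviruses, none hypomethylated),
#' IAPLTR2 (15 solo + 5 proviruses, 5 hypomethylated in tail), IAPLTR2a2
#' (35 solo + 5 proviruses, 11 hypomethylated in sperm; with the provirus
#' LTRs this yields the 11 + 34 = 45-sequence composition used for
#' clustering) and IAPEY (22 solo + 4 proviruses, 8 hypomethylated
#' in sperm).
#'
#' @return data.frame copy plan.
#' @export
defaultCopyPlan <- function() {
  data.frame(
    subfamily = c("IAPLTR1", "IAPLTR2", "IAPLTR2a2", "IAPEY"),
    n_solo = c(8L, 15L, 35L, 22L),
    n_full = c(6L, 5L, 5L, 4L),
    n_hypo = c(0L, 5L, 11L, 8L),
    hypo_tissue = c(NA, "tail", "sperm", "sperm"),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "SimConfig", function(object) {
  cp <- object@copy_plan
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  copies: ", sum(cp$n_solo) + 2L * sum(cp$n_full), " LTRs (",
      sum(cp$n_solo), " solo + ", sum(cp$n_full), " proviruses) across ",
      nrow(cp), " subfamilies; ", sum(cp$n_hypo), " hypomethylated\n", sep = "")
  cat("  tissues: ", paste(object@tissues, collapse = ", "), "\n", sep = "")
  cat("  library: fragments ", object@fragment_range[1], "-",
      object@fragment_range[2], " bp, ", object@read_length,
      "-bp paired reads, ", object@molecules_per_copy,
      " molecules/copy/tissue\n", sep = "")
  cat("  conversion rate ", object@conversion_rate,
      ", per-copy mutation rate ", object@mutation_rate, "\n", sep = "")
})

#' @describeIn SimConfig-class master seed accessor
#' @param object A SimConfig.
#' @export
simSeed <- function(object) object@seed

#' @describeIn SimConfig-class copy plan accessor
#' @export
copyPlan <- function(object) object@copy_plan

#' @describeIn SimConfig-class tissue labels accessor
#' @export
simTissues <- function(object) object@tissues

#' Position weight matrix model of a TF-binding motif
#'
#' A probability matrix over A,C,G,T per motif position, a 0-order
#' background, and a p-value threshold for reporting scan hits.  Scores are
#' log2 likelihood ratios against the background; p-values come from the
#' exact null score distribution (dynamic programming over discretised
#' scores).
#'
#' @name MotifModel-class
#' @rdname MotifModel-class
#' @exportClass MotifModel
setClass("MotifModel", representation(
  name = "character",
  matrix = "matrix",          # 4 x L, rows A,C,G,T, columns sum to 1
  background = "numeric",     # length 4, sums to 1
  pseudocount = "numeric",
  pvalue_threshold = "numeric"
))

setValidity("MotifModel", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L) msg <- c(msg, "matrix must have 4 rows (A,C,G,T)")
  if (!isTRUE(all.equal(unname(colSums(m)), rep(1, ncol(m)), tolerance = 1e-6)))
    msg <- c(msg, "matrix columns must each sum to 1")
  if (length(object@background) != 4L ||
      !isTRUE(all.equal(sum(object@background), 1, tolerance = 1e-6)))
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (any(m < 0) || any(object@background < 0)) msg <- c(msg, "negative probabilities")
  if (object@pvalue_threshold <= 0 || object@pvalue_threshold > 1)
    msg <- c(msg, "pvalue_threshold must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a MotifModel
#'
#' @param name Motif label.
#' @param matrix 4 x L probability (or count) matrix, rows in A,C,G,T
#'   order; counts are normalised after adding `pseudocount`.
#' @param background Length-4 background frequencies (A,C,G,T).
#' @param pseudocount Added to every cell before normalisation.
#' @param pvalue_threshold Report scan hits with p below this.
#' @return A \linkS4class{MotifModel}.
#' @examples
#' m <- motifModel("toy", matrix(c(1, 0, 0, 0), nrow = 4,
#'                               dimnames = list(c("A", "C", "G", "T"), NULL)))
#' motifLength(m)
#' @export
motifModel <- function(name, matrix, background = rep(0.25, 4),
                       pseudocount = 0.001, pvalue_threshold = 1e-4) {
  matrix <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  rownames(matrix) <- c("A", "C", "G", "T")
  new("MotifModel", name = name, matrix = matrix,
      background = background / sum(background),
      pseudocount = pseudocount, pvalue_threshold = pvalue_threshold)
}

#' @describeIn MotifModel-class motif label
#' @param object A MotifModel.
#' @export
motifName <- function(object) object@name

#' @describeIn MotifModel-class probability matrix (4 x L)
#' @export
motifMatrix <- function(object) object@matrix

#' @describeIn MotifModel-class motif length in bp
#' @export
motifLength <- function(object) ncol(object@matrix)

#' @describeIn MotifModel-class background frequencies
#' @export
motifBackground <- function(object) object@background

setMethod("show", "MotifModel", function(object) {
  cons <- paste(rownames(object@matrix)[apply(object@matrix, 2, which.max)],
                collapse = "")
  cat("MotifModel '", object@name, "': ", motifLength(object),
      " bp, consensus ", cons, ", p-threshold ", object@pvalue_threshold,
      "\n", sep = "")
})

#' Bisulfite-reduced genome index
#'
#' Stores the genome together with its two reduced-alphabet images: C->T
#' (where fully converted top-strand fragments align) and G->A (where
#' bottom-strand-derived fragments align after projection).  Lookup is
#' mismatch-tolerant substring search on the reductions; coordinates map
#' one-to-one back to the original genome.
#'
#' @name ReducedIndex-class
#' @rdname ReducedIndex-class
#' @exportClass ReducedIndex
setClass("ReducedIndex", representation(
  genome = "DNAStringSet",
  ct = "DNAStringSet",
  ga = "DNAStringSet",
  ct_cat = "DNAString",     # contigs joined by N spacers for one-pass search
  ga_cat = "DNAString",
  cat_offset = "integer"    # start of each contig within the joined string
))

setValidity("ReducedIndex", function(object) {
  if (length(object@genome) == 0L) return("empty genome")
  if (!identical(S4Vectors::width(object@genome), S4Vectors::width(object@ct)) ||
      !identical(S4Vectors::width(object@genome), S4Vectors::width(object@ga)))
    return("reductions must mirror genome widths")
  TRUE
})

setMethod("show", "ReducedIndex", function(object) {
  cat("ReducedIndex over ", length(object@genome), " contig(s), ",
      sum(S4Vectors::width(object@genome)), " bp (C->T and G->A reductions)\n",
      sep = "")
})

#' @describeIn ReducedIndex-class the indexed genome
#' @param object A ReducedIndex.
#' @export
indexGenome <- function(object) object@genome

#' Derive a stage-specific random seed from the master seed
#'
#' Keeps independent random streams per pipeline stage while remaining a
#' pure function of the master seed (kept below 2^31).
#' @keywords internal
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}
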