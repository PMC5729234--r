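## fully convert a sequence in silico: every non-CpG C -> T (CpG cytosines
## are left as C, i.e. treated as methylated; primer sites are CpG-free so
## this choice does not affect targetability)
convertFullTop <- function(seq) gsub("C(?!G)", "T", seq, perl = TRUE)

#' In-silico primer targetability of LTR copies
#'
#' Checks, per copy, whether each IAP primer still matches its
#' bisulfite-converted sequence (IAP-BS2 against the converted sense
#' strand, IAP-BS1 against the converted antisense strand) with at most
#' `max_mismatch` IUPAC-aware mismatches, and summarises the targetable
#' fraction per subfamily.
#'
#' @param sequences [Biostrings::DNAStringSet] or character vector of LTR
#'   copy sequences in element orientation (e.g. from [copySequences()]).
#' @param subfamilies Optional character vector (same length) for the
#'   per-subfamily summary.
#' @param primers Primer list as [tepbatPrimers()].
#' @param max_mismatch Tolerance (default 2).
#' @return List: `per_copy` (copy, subfamily, bs1, bs2, targetable) and
#'   `per_subfamily` (subfamily, n, frac_targetable).
#' @export
insilicoPrimerTargets <- function(sequences, subfamilies = NULL,
                                  primers = tepbatPrimers(),
                                  max_mismatch = 2L) {
  assertIupac(unlist(primers))
  if (is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(subfamilies)) subfamilies <- rep("all", length(sequences))
  hitAnywhere <- function(primer, subject) {
    Biostrings::countPattern(primer, Biostrings::DNAString(subject),
                             max.mismatch = max_mismatch,
                             fixed = c(pattern = FALSE, subject = TRUE)) > 0L
  }
  bs1 <- bs2 <- logical(length(sequences))
  for (i in seq_along(sequences)) {
    sense <- convertFullTop(sequences[i])
    anti <- convertFullTop(revComp(sequences[i]))
    bs2[i] <- hitAnywhere(primers$bs2, sense)
    bs1[i] <- hitAnywhere(primers$bs1, anti)
  }
  per_copy <- data.frame(
    copy = if (!is.null(names(sequences))) names(sequences)
           else as.character(seq_along(sequences)),
    subfamily = subfamilies, bs1 = bs1, bs2 = bs2,
    targetable = bs1 | bs2, stringsAsFactors = FALSE)
  per_sf <- do.call(rbind, lapply(split(per_copy, per_copy$subfamily),
    function(d) data.frame(subfamily = d$subfamily[1], n = nrow(d),
                           frac_targetable = mean(d$targetable),
                           stringsAsFactors = FALSE)))
  rownames(per_sf) <- NULL
  list(per_copy = per_copy, per_subfamily = per_sf)
}

#' Read / write a simulation config as YAML
#'
#' Flat key-value file mirroring the \linkS4class{SimConfig} constructor
#' arguments; `copy_plan` is a list of records.
#' @param file Path.
#' @return `readSimConfig` returns a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$copy_plan)) {
    y$copy_plan <- do.call(rbind, lapply(y$copy_plan, function(r)
      data.frame(subfamily = r$subfamily, n_solo = as.integer(r$n_solo),
                 n_full = as.integer(r$n_full), n_hypo = as.integer(r$n_hypo),
                 hypo_tissue = if (is.null(r$hypo_tissue)) NA_character_
                               else r$hypo_tissue,
                 stringsAsFactors = FALSE)))
  }
  do.call(simConfig, y)
}

#' @rdname readSimConfig
#' @param config A \linkS4class{SimConfig}.
#' @export
writeSimConfig <- function(config, file) {
  cp <- config@copy_plan
  y <- list(
    seed = config@seed,
    copy_plan = lapply(seq_len(nrow(cp)), function(i) {
      r <- as.list(cp[i, ]); if (is.na(r$hypo_tissue)) r$hypo_tissue <- NULL; r
    }),
    tissues = config@tissues, n_hypo_both = config@n_hypo_both,
    flank_length = config@flank_length, mutation_rate = config@mutation_rate,
    conversion_rate = config@conversion_rate,
    fragment_range = config@fragment_range, read_length = config@read_length,
    molecules_per_copy = config@molecules_per_copy,
    hyper_shape = config@hyper_shape, hypo_max = config@hypo_max,
    hypo_shape = config@hypo_shape, flank_meth_level = config@flank_meth_level,
    cpg_jitter_sd = config@cpg_jitter_sd, seq_error_rate = config@seq_error_rate,
    base_quality = config@base_quality)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Run the full TEPBAT simulation-and-analysis pipeline
#'
#' simulate -> trim -> map -> call -> aggregate -> annotate features ->
#' comparative summaries -> clade/motif analysis, with per-stage counters
#' and (optionally) all stage outputs written under `outdir`.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param outdir Output directory, or NULL to keep everything in memory.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param min_calls Per-copy call-count filter.
#' @param min_support Clade support threshold (fraction of replicates).
#' @param max_n_hyper Hypermethylated copies sampled per clade analysis.
#' @param motifs Motif models for the enrichment stage (default: the
#'   built-in synthetic motif set).
#' @param verbose Print stage accounting.
#' @return List of class `TepbatRun`: sim, truth, reads, trimmed, mapped,
#'   calls, records, annotated, pairs, joint, summaries (per tissue),
#'   clades (per tissue), manifest.
#' @export
runPipeline <- function(config, outdir = NULL,
                        bootstrap_replicates = 1000L,
                        min_calls = 20L, min_support = 0.8,
                        max_n_hyper = 34L,
                        motifs = syntheticMotifs(),
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  say("stage 1/6: simulating genome, methylome and reads")
  sim <- buildGenome(config)
  truth <- assignMethylome(sim, config)
  reads <- simulateTepbatReads(sim, truth, config)

  say("stage 2/6: trimming (", nrow(reads$reads), " pairs)")
  trimmed <- trimReadPairs(reads$reads)
  frac_tag_primer <- mean(trimmed$tag_detected &
                          trimmed$primer_detected != "none")

  say("stage 3/6: mapping")
  index <- buildReducedIndex(sim$genome)
  mapped <- mapReadPairs(trimmed, index,
                         fragment_range = config@fragment_range)
  stopifnot(mapped$counts["pairs_in"] ==
            mapped$counts["pairs_unique"] + mapped$counts["pairs_discarded"])
  say("  unique pairs: ", mapped$counts["pairs_unique"], " / ",
      mapped$counts["pairs_in"])

  say("stage 4/6: methylation calling and per-copy aggregation")
  calls <- callMethylation(mapped$alignments, sim$genome)
  records <- aggregateLtrMethylation(calls, sim$annotation,
                                     min_calls = min_calls)

  say("stage 5/6: feature annotation and comparative summaries")
  annotated <- annotateLtrFeatures(sim$annotation)
  pairs <- elementLtrPairs(annotated)
  ## use recomputed features downstream
  feat <- S4Vectors::mcols(annotated)$feature[
    match(records$copy_id, S4Vectors::mcols(annotated)$copy_id)]
  records$feature <- ifelse(is.na(feat), records$feature, feat)
  joint <- jointTissueTable(records, min_calls = min_calls)
  summaries <- list()
  for (t in config@tissues) {
    hypo <- joint[joint[[paste0("bin_", t)]] == "low", , drop = FALSE]
    summaries[[t]] <- list(
      bins = binCounts(joint, t),
      hypo_subfamilies = subfamilyDistribution(hypo),
      solo_enrichment = featureEnrichment(joint, t, "solo"),
      concordance = ltrPairConcordance(joint, pairs, t))
  }
  summaries$subfamily_levels <- subfamilySummary(joint)

  say("stage 6/6: clade and motif analysis")
  clades <- list()
  for (t in config@tissues) {
    bins <- joint[[paste0("bin_", t)]]
    hypo_ids <- joint$copy_id[bins == "low"]
    if (length(hypo_ids) < 3L) { clades[[t]] <- NULL; next }
    sf <- names(sort(table(joint$subfamily[joint$copy_id %in% hypo_ids]),
                     decreasing = TRUE))[1]
    hypo_sf <- joint$copy_id[bins == "low" & joint$subfamily == sf]
    hyper_sf <- joint$copy_id[bins != "low" & joint$subfamily == sf]
    set.seed(deriveSeed(config@seed, paste0("cladepick_", t)))
    hyper_sf <- sample(hyper_sf, min(max_n_hyper, length(hyper_sf)))
    ids <- c(hypo_sf, hyper_sf)
    seqs <- copySequences(sim$genome, sim$annotation, ids)
    aln <- alignmentFromSequences(seqs)
    st <- bootstrapSupport(aln, replicates = bootstrap_replicates,
                           seed = deriveSeed(config@seed, paste0("boot_", t)))
    status <- stats::setNames(ifelse(ids %in% hypo_sf, "hypo", "hyper"), ids)
    clade <- findHypomethylatedClade(st, status, min_support = min_support)
    in_clade <- names(status) %in% clade$members
    enr <- cladeMotifEnrichment(
      list(clade = as.character(seqs[ids[in_clade]]),
           rest = as.character(seqs[ids[!in_clade]])), motifs)
    dens <- cpgDensityByClade(
      list(clade = as.character(seqs[ids[in_clade]]),
           rest = as.character(seqs[ids[!in_clade]])), motifs)
    clades[[t]] <- list(tissue = t, subfamily = sf, tree = st,
                        status = status, clade = clade,
                        motif_enrichment = enr, cpg_density = dens)
  }

  counters <- c(
    molecules_dropped_primer = reads$dropped_primer,
    pairs_simulated = nrow(reads$reads),
    frac_tag_and_primer = frac_tag_primer,
    mapped$counts,
    copies_pass_filter = nrow(joint),
    ltr_copies = sum(S4Vectors::mcols(sim$annotation)$class == "ltr"))
  manifest <- list(
    seed = config@seed,
    config = utils::capture.output(show(config)),
    counters = as.list(counters),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- list(sim = sim, truth = truth, reads = reads, trimmed = trimmed,
              mapped = mapped, calls = calls, records = records,
              annotated = annotated, pairs = pairs, joint = joint,
              summaries = summaries, clades = clades, manifest = manifest)
  class(run) <- c("TepbatRun", "list")
  if (!is.null(outdir)) writeRunOutputs(run, outdir)
  run
}

#' @export
print.TepbatRun <- function(x, ...) {
  cat("TepbatRun (seed ", x$manifest$seed, "): ",
      x$manifest$counters$pairs_simulated, " pairs simulated, ",
      x$manifest$counters$pairs_unique, " uniquely mapped, ",
      x$manifest$counters$copies_pass_filter,
      " copies analyzed in all tissues\n", sep = "")
  invisible(x)
}

#' Write every stage output of a pipeline run
#'
#' FASTA genome, annotation TSV + BED, truth tables, paired FASTQ, CpG
#' reports, per-copy methylation table, newick trees, motif enrichment
#' TSVs and a JSON manifest.
#'
#' @param run A `TepbatRun`.
#' @param outdir Directory.
#' @return Invisible path.
#' @export
writeRunOutputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(run$sim$genome, file.path(outdir, "genome.fa"))
  writeAnnotation(run$annotated, file.path(outdir, "annotation.tsv"))
  writeAnnotationBed(run$annotated, file.path(outdir, "annotation.bed"))
  utils::write.table(run$truth$levels, file.path(outdir, "truth_levels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$reads$truth, file.path(outdir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeTepbatFastq(run$reads, outdir)
  for (t in unique(run$calls$tissue))
    writeCpgReport(run$calls[run$calls$tissue == t, ],
                   file.path(outdir, sprintf("cpg_report_%s.tsv", t)))
  writeLtrMethylation(run$records, file.path(outdir, "ltr_methylation.tsv"))
  utils::write.table(run$joint, file.path(outdir, "joint_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in names(run$clades)) {
    cl <- run$clades[[t]]
    if (is.null(cl)) next
    writeSupportedTree(cl$tree,
                       file.path(outdir, sprintf("nj_tree_%s_%s.nwk", t, cl$subfamily)))
    utils::write.table(cl$motif_enrichment,
                       file.path(outdir, sprintf("motif_enrichment_%s.tsv", t)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
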