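---
title: "Methods: simulating and analysing targeted post-bisulfite methylomes of LTR retrotransposons"
author: "tepbat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing targeted post-bisulfite methylomes of LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepbat)
```

## The problem

Mouse IAP elements are young, high-copy LTR retrotransposons.  Their
long terminal repeats (LTRs, 300-450 bp with 15-25 CpG sites) carry the
promoter, and in most tissues the vast majority of copies are heavily
CpG-methylated.  A small minority of copies escapes methylation, sometimes
tissue-specifically, and such escapees can act as metastable epialleles.
Asking *which* copies escape requires per-copy methylation levels, which
whole-genome bisulfite sequencing only delivers at high cost because the
interesting reads are a small fraction of the library.

The targeted post-bisulfite adaptor-tagging design addressed here solves
this with an asymmetric library: after bisulfite conversion, first-strand
synthesis is primed by a *tag-plus-random* primer (a 19-nt tag followed by
a random tetramer), and the IAP-containing molecules are then amplified
with the tag primer on one side and one of two IAP-specific primers
(IAP-BS1, reverse orientation near the 5' part of the LTR; IAP-BS2,
forward orientation near the 3' part) on the other.  Each 350-450-bp
product yields a 100-bp read pair in which the primer-side read covers
repeat sequence while the tag-side read reaches into the copy's unique
flank — and is therefore mappable to a single locus.  This package
implements the full analysis of such experiments, plus a synthetic-data
generator so every stage is testable without any external download.

## The synthetic-data generator

`simConfig()` + `buildGenome()` + `assignMethylome()` +
`simulateTepbatReads()` emulate the study conditions at desk scale:

* **Genome.** Four LTR subfamily consensus sequences (`defaultConsensi()`,
  320-345 bp, each constrained to 15-25 CpGs) and one 1.8-kb internal
  consensus are generated deterministically in code; they are synthetic
  stand-ins, not database consensus sequences.  Copies are planted as solo
  LTRs or complete proviruses (5' LTR - internal - 3' LTR on one strand)
  inside 600-bp unique random flanks, with independent per-copy
  substitutions at 2% per base (the configured `mutation_rate`), and laid
  out in shuffled order on three chromosomes.  The default copy plan
  (`defaultCopyPlan()`) plants 120 LTR copies; IAPLTR2a2 contributes
  45 copies so that the clade analysis runs at the same sequence count
  as the motivating study.
* **Primer sites.** Each consensus carries fixed pre-images of the two
  primers such that, after full bisulfite conversion of non-CpG cytosines,
  IAP-BS2 matches the sense strand exactly and IAP-BS1 matches the
  antisense strand (its IUPAC W realised as A).  Both sites are CpG-free,
  so primer annealing is independent of methylation state — as in the real
  primer design.  BS1 sits at ~0.38 of the LTR pointing towards the 5'
  end, BS2 at ~0.82 pointing towards the 3' end; the R region between them
  hosts the clade profile (below).  With 2% per-copy divergence and the
  2-mismatch annealing tolerance, >97% of copies remain targetable, which
  the in-silico check `insilicoPrimerTargets()` reproduces.
* **Methylome.** Per copy and tissue, a copy-level mean is drawn from
  Beta(27, 3) (mean 0.9) for hypermethylated copies or from
  0.2 x Beta(1.5, 6) for hypomethylated copies, so hypomethylated levels
  lie within [0, 0.2] by construction.  Per-CpG truth equals the copy mean
  (optional jitter via `cpg_jitter_sd`), which makes estimator tests
  exact.  Hypomethylation is tissue-specific (IAPLTR2a2 and IAPEY in
  sperm, IAPLTR2 in tail by default) with 3 copies hypomethylated in both
  tissues, and is planted only in solo copies, reflecting the observation
  that hypomethylated loci are predominantly solo LTRs.  Flanking
  (non-repeat) CpGs get a constant level (default 0.75).
* **Clade profile.** The hypomethylated copies of a subfamily additionally
  share 12 diagnostic substitutions in U3 and a planted R-region block:
  two Maz-like (`GGGAGGGG`) and one Ubp1-like (`CTGGTTACAT`) motif
  instances plus three extra CpG dyads adjacent to them.  This gives the
  neighbor-joining stage a recoverable clade, the motif stage a
  clade-specific signal, and the CpG-density stage its "more CpGs near
  motifs" contrast.  Per-copy mutations avoid these planted positions on
  clade members so the planted truth is well-defined.
* **Reads.** Per molecule: a library side is drawn (BS1/BS2 with equal
  probability, which also selects the template strand, making the library
  non-directional); the template is converted (CpG cytosine stays C with
  its truth probability, every other cytosine converts with
  `conversion_rate`, default 0.995); the molecule is kept only if the IAP
  primer still matches its site with <= 2 IUPAC-aware mismatches; the
  fragment length is uniform on 350-450 bp; read 2 starts with the
  incorporated primer, read 1 with the tag plus the four genomic
  tetramer-matched bases.  Qualities are constant Q37 by default, with a
  uniform substitution-error option.  No PCR duplicates, chimeras or
  indels are modelled.

What passing tests on these data do **not** show: robustness to indels and
structural variants, to diverged or fragmented RepeatMasker annotations,
to PCR duplicates/bias, or to genuine within-copy methylation
heterogeneity.  The generator's value is that every downstream number has
a planted ground truth.

## Mapping under reduced alphabets

`buildReducedIndex()` stores the genome's C→T and G→A images.  A read is
looked up under four combinations (each image, each orientation), exactly
the strategy space of standard bisulfite aligners for a non-directional
library.  Candidate placements come from pigeonhole seeding — with at most
3 mismatches, one of four disjoint 16-mers must match exactly, and all
seeds of all reads are matched in one pass with a `PDict` — and are
verified at full length.

The unique-anchor rule: the tag-side read is the anchor, because by
design it extends into unique flank.  A pair is placed only when the
anchor has exactly one best-mismatch location (<= 3 mismatches,
substitution-only, since the generator plants no indels); ties discard
the pair as `multi_hit`, mirroring the discard-multi-hit behaviour of the
original workflow.  The primer-side mate is then required to land on the
consistent strand combination within the fragment-length bound, else the
pair is discarded as `mate_inconsistent`.  Anchors deriving from provirus
LTR amplicons that extend into the shared internal sequence are the main
source of multi-hits — the package's qualitative analogue of the low
mapping efficiency of repeat-flanked copies.

`callMethylation()` walks each placed read: a C over a genomic CpG
cytosine (or projected G over the dyad's G for bottom-strand reads) is a
methylated call, T (or A) unmethylated, anything else ignored; dyads are
collapsed onto the + strand C position (cytosine-report convention), so
aggregation is strand-free.

## Per-copy levels, filtering and binning

`aggregateLtrMethylation()` averages per-site levels
meth/(meth+unmeth) over the CpG sites inside each annotated LTR.  The
primary statistic is the unweighted mean of site levels; the pooled-calls
ratio is available via `statistic = "pooled"` because the two phrasings
("averaged" per site vs dividing summed calls) coexist in the field and
differ when site depths are unequal.  Copies with fewer than 20 total
calls (summed depth over CpG sites) are excluded — 19 calls fail,
20 pass.  Levels are binned low (<= 0.2), medium ((0.2, 0.8]) and high
(> 0.8); 0.8 itself is medium.  `jointTissueTable()` restricts to copies
passing the filter in every tissue, which is the universe for all
comparative statistics.

A note on the recovery tests: with per-CpG truth equal to the copy mean,
the pooled estimator is exactly binomial, so the 3-sigma bound
`3 * sqrt(p(1-p)/total_calls)` is evaluated on the pooled statistic; the
mean-of-sites statistic has slightly larger variance under unequal site
depths.  A 0.02 absolute floor guards the bound where p(1-p) is tiny.

## LTR structure annotation

`annotateLtrFeatures()` automates the 5'/3'/solo labelling: an LTR
adjacent (within `gap_tolerance`, default 1000 bp, since annotation
pipelines frequently split elements) to an internal fragment on the same
strand is a provirus LTR — `five_prime` when the internal lies on its
element-3' side (genomic right on +, left on −) — and the two LTRs
flanking one contiguous internal run share an `element_id`.  Everything
else is solo; an LTR with unpaired internal fragments on both sides is
left `unassigned` with a warning rather than silently resolved.  Nested
insertions are not resolved.

## Comparative statistics

Counts and integer percentages (rounded half away from zero, the
convention of copy-count figure legends) come from `binCounts()`,
`subfamilyDistribution()` and `percentReport()`.  "Significantly
enriched" is operationalised as a two-sided Fisher exact test on the
2x2 table (hypomethylated vs not) x (feature vs rest) with BH correction
where several categories are tested; the reported odds ratio is the
sample odds ratio ad/bc.  `ltrPairConcordance()` reports per-element 5'
vs 3' LTR levels and counts strongly discordant pairs (one <= 0.2, the
other > 0.8).

## Clades and motifs

Sequences of one subfamily are compared by p-distance with pairwise gap
deletion (a deliberate, stated choice; the distance model behind the
original trees is not recorded).  `neighborJoining()` is the Saitou-Nei
agglomeration with the Q-criterion, standard branch-length formulas,
negative lengths clamped to zero and a deterministic tie-break on the
smallest index pair; on additive matrices it provably recovers the
generating topology, which the tests exercise against a path-length
oracle and against the independent implementation in ape.
`bootstrapSupport()` resamples alignment columns (1000 replicates in the
standard workflow) and counts bipartition recovery.  The hypomethylated
clade is, among bipartitions with support >= 80% of replicates (chosen
to sit just below the >86% supports observed in the motivating study),
the side with the most hypomethylated leaves — ties broken by
hypomethylated fraction, then by smaller clade; with no supported edge
the whole tree is returned with a warning.  Simulated copies of one
subfamily are equal-length by construction (substitutions only) and are
therefore consumed as a ready alignment; real sequences must be supplied
pre-aligned.

Motif scanning is FIMO-like: log2 likelihood-ratio scores against a
0-order background (estimated from the scanned sequences by default),
both strands, with per-hit p-values from the exact null distribution of
the discretised score (1/1000-bit bins, zero-probability cells floored
at -20 bits) computed by dynamic programming — tested for exact equality
against brute-force enumeration for motif lengths <= 6.  The default
report threshold is p < 1e-4.  Clade enrichment is presence/absence
(>= 1 hit) per sequence, Fisher exact across clades, BH-corrected;
q < 0.05 is called enriched.  `cpgDensityByClade()` counts CpGs per
sequence overall and within +/- 50 bp of motif hits and compares clades
with a rank-sum test.  The bundled `inst/extdata/synthetic_motifs.meme`
holds the two synthetic planted PWMs; real JASPAR/HOCOMOCO matrices can
be supplied in the same MEME text format.

## The pipeline and reproducibility

`runPipeline()` chains the stages, checks read conservation at every
boundary (pairs in = uniquely mapped + discarded, by reason), and writes
all stage outputs in plain-text formats (FASTA, BED6 + 1-based TSV
annotation, Phred+33 FASTQ, cytosine-report TSV, newick with support
labels, JSON manifest).  One master seed fans out to fixed per-stage
seeds, so a run is bit-reproducible and stages are individually
reproducible; `readSimConfig()`/`writeSimConfig()` round-trip the
configuration as YAML.  Stages communicate only through these documented
files, so an externally produced CpG report or annotation can replace
the bundled simulator or mapper at any boundary.

Problem sizes used by the shipped checks are deliberate desk-scale
choices: the default simulation plants 120 LTR copies with 30 molecules
per copy and tissue (~7000 read pairs, average per-copy call totals in
the low hundreds), the NJ bootstrap uses up to 1000 replicates on 45
sequences, and the brute-force mapper oracle runs on a 50-kb genome.
The genome-wide copy counts of the motivating study (thousands of
copies, depth ~320) are not reproducible from scratch without its
unreleased sequencing data; the package's claims are therefore about
planted-truth recovery, not about those genome-wide totals.

## Known limitations

* Substitution-only alignment (no indels, no gapped alignment, no
  SAM/BAM emission, no duplicate marking, CpG context only).
* The manual structural annotation of the original study has no recorded
  rule; automated labels can disagree with manual ones at edge cases and
  are flagged, not silently resolved.
* The per-LTR level definition is ambiguous between mean-of-sites and
  pooled calls in the field's wording; both are implemented,
  mean-of-sites is the default.
* The motif stage ships synthetic PWMs for its planted ground truth; it
  does not attempt motif discovery, and negative results (a clade without
  clade-specific motifs, as seen for IAPEY-like cases) are reported as
  empty enrichment tables, not errors.
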