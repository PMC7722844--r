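---
title: "silentscan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{silentscan: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made. Every empirical
statement here is one the test suite or `scripts/acceptance.R` computes;
nothing is asserted from memory.

## The study design the package serves

A transgene-silencing study in *Chlamydomonas* typically contrasts a
progenitor strain with derived expression mutants (and optionally
complemented lines) across several data types: whole-genome resequencing
(transposon mobility, causal-variant triage), RNA-seq (endogenous
transcriptome effects), ChIP-qPCR (chromatin state at transgene
insertion sites), a genetic mapping/complementation screen, and protein
phylogenetics of the candidate gene family. `silentscan` implements the
quantitative step of each arm, plus generators that fabricate each arm's
inputs with known ground truth, so the pipeline's behaviour is testable
end to end without any external accession.

## Transposon survey

**Model.** A TE/genome junction produces read pairs with one mate inside
the element and one mate in flanking genomic sequence. Aligned against
the TE consensus set alone, such pairs are *half-mapped*; their unmapped
mates (*anchors*), re-mapped to the genome, pile up at the junction.
Loci are maximal nonzero-coverage intervals of pooled anchors after
merging gaps ≤ `merge_distance`, kept when supported by
≥ `min_locus_reads` distinct reads.

**Parameters.** All three thresholds default to 10 reads —
locus calling (pooled), per-strain presence, and the max/min differential
ratio. `merge_distance` defaults to 200 bp ≈ two read lengths: left- and
right-flank anchor clusters of one insertion abut at the junction, so any
merge distance ≥ 0 joins them, while 200 bp also absorbs small coverage
gaps without fusing insertions ≥ 1 kb apart.

**Open choices made here.**

* *Pooled vs per-strain locus threshold*: the locus-calling threshold is
  applied to the counts pooled over strains (alignments are merged before
  coverage is computed), the presence threshold per strain. A shared
  insertion then needs only ~3 reads per strain in a 4-strain pool to be
  called, but ≥ 10 in a given strain to be *present* there.
* *"Reads" means distinct reads*: duplicate anchor identifiers are
  collapsed per strain before counting; interval support is the number of
  distinct anchor reads overlapping the interval, not per-base depth.
* *Zero minimum in the differential ratio*: max/0 is treated as infinite
  and flagged whenever the maximum reaches the presence threshold. A locus
  robustly covered in one strain and empty in another is exactly a
  candidate transposition; requiring max ≥ presence_threshold prevents
  noise loci (e.g. 3/0/0/0) from being flagged.
* The survey's manual curation step (inspecting flagged loci in a genome
  browser) is replaced by the deterministic flag; curation is out of
  scope.

**Pattern classes.** The summary assigns each locus to exactly one class:
present in all strains, present in exactly one strain (one class per
strain), present in all strains except the first of the roster (the
"shared by derived strains" pattern), or `other`. Row-sum conservation
(per-TE total = sum of class counts) is asserted on every run.

## The built-in mapper

Ungapped seed-and-extend, k = 15 seeds at every read offset, candidates
scored by full Hamming distance on both strands, mismatch budget
`floor(0.06 × read length)`. Two deliberate conservatisms: a read whose
best placement ties with its second best is left unmapped (a false anchor
is worse than a lost anchor), and gapped alignment is not attempted (the
simulator plants substitutions only, and the survey consumes
mapped/unmapped status plus position, not CIGAR detail). With ≤ 5
mismatches in a 100-mer a clean 15-mer seed always exists (pigeonhole:
max clean gap ≥ ⌈95/6⌉ = 16 > 15), so the all-offset seeding is exhaustive
there; at exactly 6 mismatches a pathological spacing can in principle
evade every seed, which the Hamming-oracle property test avoids by
planting ≤ 4 mismatches. Coordinates are 0-based half-open internally and
1-based in SAM, per the two standards.

## Variant triage and CAPS design

Selection keeps records with the progenitor homozygous reference and ≥ 1
mutant carrying the alternate; a missing progenitor genotype disqualifies
the record (the rule requires positive evidence of reference state).
Genotypes containing any alt allele index count as carries-alt — the
organism is haploid but callers may emit diploid-style calls.
Multi-allelic records are split into biallelic rows on reading. "Genes hit
in both mutants" requires a passing variant *private* to each mutant and
distinct between them, where distinct means a different (chrom, pos, alt)
triple — the stricter reading of "distinct mutations"; effect classes are
matched as annotation text (case-insensitive substring against an
allow-list containing "missense" and "nonsynonymous") rather than
re-derived from gene models.

CAPS verdicts count recognition-site matches of the enzyme's IUPAC
pattern on both strands of the reference and mutated windows; forward and
reverse-strand matches at the same position (palindromic sites) count
once. Enzymes live in an editable bundled table
(`extdata/enzymes.tsv`), not in code.

## Differential expression

FPKM uses the closed form count/(length/10³)/(total/10⁶). Library size
factors are median-of-ratios against the geometric-mean pseudo-reference
(zero-containing genes excluded from estimation). Note an identifiability
nuance the tests pin down: scaling one of n samples by k multiplies all
size factors' *absolute* values by k^(1/n) (the pseudo-reference moves),
so only size-factor ratios — and hence between-sample comparisons — are
exactly invariant; the absolute normalized scale is a convention.

The per-gene test is a declared stand-in for count-model inference, not a
re-implementation of it: a two-sided location test on
log₂(normalized + ½), with per-gene pooled variances shrunk toward a
lowess mean-variance trend by an empirical-Bayes F prior (method of
moments on log sample variances; the prior df solves
trigamma(d₀/2) = var(log s²) − trigamma(d/2)). The shrinkage is the one
deliberate departure from the plainest possible test: at 3–4 replicates
per group an unmoderated Welch test cannot push true |log₂FC| = 2 genes
past a strict BH-adjusted 0.01 cutoff with useful power (measured during
development at 10–40% recovery), which is precisely why the field
moderates variances at these sample sizes. The acceptance suite measures
both sides of the bargain on synthetic data: empirical FDR on null
simulations and recovery of planted fold-changes. Equality with any
published DEG count is *not* claimed anywhere — those numbers depend on
external accessions and tool versions.

Genes with zero counts in all samples report log₂FC 0, p 1, and are
excluded from the BH denominator. BH itself is the textbook step-up,
tested elementwise against a brute-force implementation and `p.adjust`.
DEG thresholds are strict inequalities exactly as configured; a gene at
log₂FC = 1.0 is not a DEG. The 4-way Venn reports the full 15-region
decomposition alongside the intersection.

## ChIP-qPCR

percent-of-input = 100 · f · E^(Cq_input − Cq_IP). Defaults f = 0.10 and
E = 2 (perfect doubling); per-assay efficiencies are overridable but not
estimated — standard-curve fitting is out of scope. Normalization to the
reference region happens per replicate, then replicates are averaged
(mean, SD, SE): the alternative order (average, then divide) is not
distinguishable from published descriptions, and per-replicate
normalization is the variant that propagates replicate-level variation
into the reported SE. Significance testing of enrichment differences is
routine statistics and out of scope.

## Screen genetics

The deliberate threshold asymmetry: expression phenotype at ≥ 30%
YFP-positive (inclusive), complementation at YET < 30% (strict), so a
line at exactly 30% has the phenotype and is not complemented. YET
percentages round half away from zero to one decimal (reporting-grade
rounding, not banker's); the four complementation classes are contiguous
integer bins applied to the rounded value (10.0 falls in 1–10). Class
counts, not rounded percentages, carry the total-vs-breakdown consistency
check. RF on a phenotype-selected population is one-sided (every
segregant carries the causal allele); missing genotypes leave the
denominator; no Haldane/Kosambi map-function conversion is applied.

## Phylogenetics

Distances: d = −ln(1 − p), p the fraction of differing comparable sites;
saturation (p ≥ 1) and empty comparisons are errors, not clamps. Gap
handling defaults to complete deletion (drop any column with a gap
anywhere) with pairwise deletion as an option — the published tooling's
default is not stated, so both are exposed. NJ is the standard Saitou–Nei
agglomeration; ties in the Q matrix break to the lowest (row, column)
pair for determinism; negative branch estimates are clamped to zero with
the deficit moved to the sibling edge, raw values retained in
`attr(tree, "raw_edge.length")`. Bootstrap resamples alignment columns,
skips (and tallies) replicates with saturated distances, and scores each
internal split of the point tree as the percentage of *successful*
replicates containing it; taxa are canonically sorted first so supports
are input-order invariant. NJ exactness on additive matrices is verified
against a path-length oracle to 1e-9 over random trees, with `ape::nj` as
an independent topology cross-check. A published total tree length for a
specific 34-taxon alignment is a method anchor only; reproducing it would
require that exact alignment and is not claimed.

## Synthetic data: what it emulates, what it does not

The generators state a world: a GC-configurable i.i.d. backbone; full-
length TE insertions (no truncation, no nesting) shared or strain-
specific; 100+100 nt pairs with normal fragment lengths truncated at two
read lengths, uniform substitution errors (no indels), constant quality
strings; NB counts with planted log₂ fold-changes; Cq tables whose
expected percent-input equals the designed enrichment; segregant
genotypes where each marker allele is non-recombinant with probability
1 − RF. Everything is seeded and bit-reproducible, and every generator
returns its truth table.

What this validates: threshold logic, interval algebra, coordinate
lifting, estimator recovery, determinism. What it cannot validate:
repeat-induced mapping ambiguity (the backbone has no endogenous TE
copies or segmental duplications), indel/structural read errors,
GC-dependent coverage bias, overdispersion structure beyond a single NB
dispersion, linked markers on a real genetic map. A green end-to-end test
therefore establishes the pipeline's correctness on its stated model, not
concordance with any particular sequencing run.

The demonstration config uses 20× coverage on a 60 kb backbone: at the
survey's fixed presence threshold of 10 reads, ~20 expected anchors per
strain per insertion keep the demo's truth-recovery checks comfortably
powered without tuning any threshold.

## Numerical and interface choices

* All randomness flows from explicit integer seeds; per-stage seeds are
  derived arithmetically from one root seed and stay below 2³¹.
* The pipeline config file is JSON (jsonlite), not YAML: no YAML parser
  is part of the package's dependency footprint, and the structure is
  identical.
* SAM text is written/parsed directly (it is a plain TSV dialect; the
  BAM-centric infrastructure is not a dependency); reverse-strand records
  store the reverse-complemented sequence per the standard and are
  restored to read orientation on reading.
* Tables are TSV with headers; BED-style intervals are 0-based half-open;
  VCF positions 1-based, per the standards.

## Known limitations

The mapper is single-threaded, ungapped, and not a BWA substitute; exact
concordance with any external aligner is not claimed. The DEG stand-in is
not a dispersion-shrinkage count model and should not be used for real
inference where DESeq2/edgeR/limma apply. CAPS design does not handle
indel variants or design primers. Bootstrap supports below ~4 taxa are
vacuous (no internal splits). The real-accession survey targets (hundreds
of loci across four resequenced strains) require external downloads and
an external aligner and are deliberately outside the test surface.
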