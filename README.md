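# silentscan

Computational toolkit for multi-strain studies of epigenetic transgene
silencing in *Chlamydomonas reinhardtii* — the kind of study that asks
whether a silencing mutation (here, loss-of-function alleles of a
sirtuin-type histone deacetylase) releases transposons, changes the
transcriptome, alters chromatin at transgene insertion sites, and where
the causal locus maps.

It is aimed at bench-and-bioinformatics groups who have per-strain
short-read data, qPCR tables, screen counts and protein alignments, and
want every quantitative step of such a study reproducible from the command
line or from R — including fully synthetic, seeded stand-ins for every
input so the whole pipeline can be validated against planted ground truth.

## What it computes

**Transposon mobility survey.** Read pairs are aligned to a transposon
consensus set; *half-mapped* pairs (one mate mapped to a TE, one unmapped)
are the signature of a TE/genome junction. The unmapped mate (the *anchor
read*) is re-mapped to the genome; loci are maximal intervals of pooled
anchor coverage (gaps ≤ 200 bp merged) supported by ≥ 10 distinct reads; a
TE at a locus is *present* in a strain if ≥ 10 of that strain's reads map
to it; a locus is *differential* when max/min per-strain counts ≥ 10 (a
zero minimum counts as infinite). A built-in seed-and-extend ungapped
mapper (Rcpp) makes the survey self-contained; external SAM alignments can
be substituted.

**Variant triage and CAPS markers.** From an annotated multi-strain VCF:
keep variants that are reference in the progenitor and alternate in ≥ 1
mutant; find genes with *distinct* non-synonymous variants private to each
of two mutants; and test a point variant for gain/loss of restriction
sites on both strands (CAPS genotyping markers).

**Differential expression.** FPKM = count / (length/10³) / (total/10⁶);
median-of-ratios library normalization; a moderated location test on
log₂(normalized count + ½) with empirical-Bayes variance shrinkage;
Benjamini–Hochberg step-up `q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·n/j`; DEG calls with the
strict printed thresholds (|log₂FC| > 1 ∧ p_adj < 0.01, or FC > 2 ∧ mean
FPKM > 1 ∧ p_adj < 0.01); and the 4-way directional Venn intersection that
yields candidate silencing-pathway targets.

**ChIP-qPCR.** Percent of input = 100 · f · E^(Cq_input − Cq_IP) (f = input
fraction, default 10%; E = amplification base, default 2), normalized per
replicate to a reference region (e.g. the *CYC6* promoter), then averaged
with SD/SE.

**Genetics of the screen.** Expression phenotype at ≥ 30% YFP-positive
transformants (inclusive); recombination frequency on a phenotype-selected
population (RF% = recombinants/scored, linkage at RF < 20%); YET (YFP
Expressing Transformants) scoring with the four complementation classes
(0, 1–10, 11–20, 21–29) and complementation at YET < 30%.

**Phylogenetics.** Poisson-corrected protein distances d = −ln(1 − p),
Saitou–Nei neighbor joining with deterministic tie-breaking, column
bootstrap with per-split supports, Newick output.

**Synthetic data.** Seeded generators with full ground truth: strain
genomes sharing a backbone with planted TE insertions, 100+100 nt
paired-end reads (configurable insert size/coverage/error), negative-
binomial count matrices with planted fold-changes, Cq tables with designed
enrichment, segregant genotypes with designed recombination fractions,
annotated variant tables.

## Worked example

```r
library(silentscan)

# Complementation screen: 8 lines, 20 supertransformants each
screens <- data.frame(n_yfp = c(0, 2, 3, 5, 8, 2, 0, 10), n_total = 20L)
summarize_complementation(screens)
#>   n_lines total_lt30 pct_0 pct_1_10 pct_11_20 pct_21_29 pct_ge30
#> 1       8         75    25       25      12.5      12.5       25

# 75% of lines are complemented (YET < 30%); the four class columns break
# that down; pct_ge30 are lines retaining the expression phenotype.

# CAPS marker: does a C-to-T transition at position 4 create a cut site?
design_caps_marker("AACCCGTGAA", 4, "C", "T")[2, ]
#>      enzyme   site n_ref n_mut verdict
#> BauI   BauI CACGAG     0     1    gain

# The mutation creates a BauI site (via the reverse strand, CTCGTG):
# digesting the PCR amplicon distinguishes mutant from wild type.

percent_input(19, 20)   # IP one cycle earlier than input, 10% input
#> [1] 20

# Neighbor joining on an additive toy matrix recovers the tree exactly
d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4,
            dimnames = list(letters[1:4], letters[1:4]))
tr <- nj_tree(d)
ape::write.tree(tr)            #> (c:3,d:4,(a:1,b:2):1);
total_branch_length(tr)        #> 11
```

The end-to-end demonstration (simulation → mapping → survey → triage →
DEG → ChIP → screen → phylogeny, with invariant checks and TSV/JSON
output):

```r
run_demo(default_pipeline_config(seed = 1), "demo_out")
```

or from the shell: `exec/silentscan run-demo --seed 1 --out demo_out`
(plus `map`, `te-survey`, `deg`, `chip`, `screen`, `phylo` subcommands;
run `exec/silentscan` for usage).

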