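# Cross-strain variant triage and CAPS marker design. Variants live in a
# flat VariantRecord data.frame: chrom, pos (1-based), ref, alt, gene,
# effect, plus one gt_<strain> column per strain with values in
# {ref, alt, missing}.

gt_cols <- function(variants, strains) {
  cols <- paste0("gt_", strains)
  missing <- setdiff(cols, names(variants))
  if (length(missing))
    stop("unknown strain name(s): ",
         paste(sub("^gt_", "", missing), collapse = ", "), call. = FALSE)
  cols
}

#' Read an annotated multi-strain VCF into a VariantRecord table
#'
#' Multi-allelic records are split into biallelic rows; any genotype
#' containing the row's alt allele index counts as carries-alt (haploid
#' strains, but callers may emit diploid-style genotypes). Gene and effect
#' are taken from the SnpEff-style `ANN` INFO field (fields 2 and 4) when
#' present, else from a sidecar annotation table.
#'
#' @param path VCF file.
#' @param annotations optional data.frame (`chrom`, `pos`, `alt`, `gene`,
#'   `effect`) used when the VCF has no ANN field.
#' @return VariantRecord data.frame.
#' @export
read_vcf <- function(path, annotations = NULL) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(v)$GT
  rr <- SummarizedExperiment::rowRanges(v)
  alts <- VariantAnnotation::alt(v)
  ann <- if ("ANN" %in% names(VariantAnnotation::info(v)))
    VariantAnnotation::info(v)$ANN else NULL
  rows <- list()
  for (i in seq_along(rr)) {
    alt_i <- as.character(alts[[i]])
    for (j in seq_along(alt_i)) {
      gene <- effect <- NA_character_
      if (!is.null(ann) && length(ann[[i]])) {
        fields <- strsplit(ann[[i]], "|", fixed = TRUE)
        hit <- which(vapply(fields, `[`, character(1), 1) == alt_i[j])
        if (!length(hit)) hit <- 1L
        f <- fields[[hit[1]]]
        effect <- if (length(f) >= 2) f[2] else NA_character_
        gene <- if (length(f) >= 4) f[4] else NA_character_
      }
      g <- vapply(gt[i, ], function(x) {
        al <- strsplit(x, "[/|]")[[1]]
        if (all(al == ".")) "missing"
        else if (as.character(j) %in% al) "alt"
        else "ref"
      }, character(1))
      rows[[length(rows) + 1L]] <- c(
        list(chrom = as.character(GenomicRanges::seqnames(rr)[i]),
             pos = GenomicRanges::start(rr)[i],
             ref = as.character(VariantAnnotation::ref(v)[[i]]),
             alt = alt_i[j], gene = gene, effect = effect),
        setNames(as.list(g), paste0("gt_", names(g))))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(annotations)) {
    key <- paste(out$chrom, out$pos, out$alt)
    akey <- paste(annotations$chrom, annotations$pos, annotations$alt)
    hit <- match(key, akey)
    out$gene <- ifelse(is.na(out$gene), annotations$gene[hit], out$gene)
    out$effect <- ifelse(is.na(out$effect), annotations$effect[hit], out$effect)
  }
  rownames(out) <- NULL
  out
}

#' Write a VariantRecord table as VCF
#'
#' @param variants VariantRecord data.frame (see [read_vcf()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  strains <- sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
                  "\"Functional annotations: 'Allele|Annotation|Impact|Gene'\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           sprintf("##contig=<ID=%s>", unique(variants$chrom)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strains), collapse = "\t"))
  gtm <- as.matrix(variants[, paste0("gt_", strains), drop = FALSE])
  gtv <- matrix(c(ref = "0/0", alt = "1/1", missing = "./.")[gtm],
                nrow = nrow(variants))
  ann <- sprintf("ANN=%s|%s|MODIFIER|%s", variants$alt,
                 ifelse(is.na(variants$effect), ".", variants$effect),
                 ifelse(is.na(variants$gene), ".", variants$gene))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                "50", "PASS", ann, "GT",
                apply(gtv, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Select mutant-specific variants
#'
#' Retains exactly the records where the progenitor strain is homozygous
#' reference and at least one mutant strain carries the alternate allele.
#' Records with a missing progenitor genotype are dropped: the selection
#' rule requires positive evidence of reference state.
#'
#' @param variants VariantRecord data.frame.
#' @param progenitor progenitor strain name.
#' @param mutants character vector of mutant strain names.
#' @return the retained subset.
#' @export
select_mutant_specific <- function(variants, progenitor, mutants) {
  pcol <- gt_cols(variants, progenitor)
  mcols <- gt_cols(variants, mutants)
  keep <- variants[[pcol]] == "ref" &
    rowSums(as.matrix(variants[, mcols, drop = FALSE]) == "alt") >= 1L
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes carrying distinct qualifying variants in both mutants
#'
#' Returns the genes with at least one passing variant private to mutant A
#' and at least one *distinct* passing variant (different chrom/pos/alt)
#' private to mutant B. Variants carried by both strains are not private
#' and never qualify. The effect filter matches the annotation text
#' case-insensitively against an allow-list.
#'
#' @param variants VariantRecord data.frame (typically the output of
#'   [select_mutant_specific()]).
#' @param mutant_a,mutant_b the two mutant strain names.
#' @param effects character allow-list matched against the effect
#'   annotation (substring, case-insensitive).
#' @return sorted character vector of gene identifiers.
#' @export
genes_hit_in_both <- function(variants, mutant_a, mutant_b,
                              effects = c("missense", "nonsynonymous")) {
  if (nrow(variants) == 0L) return(character(0))
  acol <- gt_cols(variants, mutant_a)
  bcol <- gt_cols(variants, mutant_b)
  pass <- !is.na(variants$effect) & !is.na(variants$gene) &
    grepl(paste(effects, collapse = "|"), variants$effect, ignore.case = TRUE)
  priv_a <- pass & variants[[acol]] == "alt" & variants[[bcol]] != "alt"
  priv_b <- pass & variants[[bcol]] == "alt" & variants[[acol]] != "alt"
  sort(intersect(unique(variants$gene[priv_a]), unique(variants$gene[priv_b])))
}

#' Bundled restriction-enzyme recognition table
#'
#' Reads the editable enzyme table shipped with the package
#' (`extdata/enzymes.tsv`): enzyme name and IUPAC recognition sequence.
#'
#' @return named character vector (enzyme -> recognition sequence).
#' @export
load_enzymes <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "silentscan")
  tab <- read_tsv(path)
  setNames(tab$site, tab$enzyme)
}

count_sites <- function(seq, site) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(site), subj, fixed = FALSE))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(rc), subj, fixed = FALSE))
  length(union(fwd, rev))  # palindromic sites counted once per position
}

#' Design a CAPS (restriction gain/loss) marker for a point variant
#'
#' Counts recognition-site occurrences on both strands of the reference
#' window and of the mutated window, and returns a gain/loss/none verdict
#' per enzyme. A gained site turns the variant into a cleavable (CAPS)
#' genotyping marker; a lost site works in the opposite orientation.
#'
#' @param window reference sequence window containing the variant.
#' @param pos 1-based variant position inside the window.
#' @param ref,alt reference and alternate base at `pos`.
#' @param enzymes named character vector of IUPAC recognition sequences
#'   (default: the bundled table, see [load_enzymes()]).
#' @return data.frame with columns `enzyme`, `site`, `n_ref`, `n_mut`,
#'   `verdict` in {gain, loss, none}.
#' @export
design_caps_marker <- function(window, pos, ref, alt, enzymes = load_enzymes()) {
  if (pos < 1 || pos > nchar(window))
    stop("variant position outside the window", call. = FALSE)
  if (toupper(substr(window, pos, pos)) != toupper(ref))
    stop("window base at 'pos' does not match 'ref'", call. = FALSE)
  mutant <- window
  substr(mutant, pos, pos) <- toupper(alt)
  n_ref <- vapply(enzymes, function(s) count_sites(window, s), integer(1))
  n_mut <- vapply(enzymes, function(s) count_sites(mutant, s), integer(1))
  data.frame(enzyme = names(enzymes), site = unname(enzymes),
             n_ref = unname(n_ref), n_mut = unname(n_mut),
             verdict = ifelse(n_mut > n_ref, "gain",
                              ifelse(n_mut < n_ref, "loss", "none")),
             stringsAsFactors = FALSE)
}
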