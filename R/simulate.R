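# Synthetic-data generators. Every generator is seeded and returns its
# ground truth alongside the data, so downstream recovery tests need no
# external files.

#' Simulate a random genome sequence
#'
#' @param length sequence length in bp (>= 1).
#' @param gc_fraction target GC content, strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @return a single character string over A/C/G/T.
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, seed = 1L) {
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(gc_fraction, "gc_fraction")
  if (length < 1) stop("'length' must be >= 1", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("'gc_fraction' must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Describe a planted transposon insertion
#'
#' One row of the design consumed by [plant_te_insertions()]. Positions are
#' 0-based coordinates on the backbone; the element is inserted *before*
#' the backbone base at `position`.
#'
#' @param te_name name of a sequence in the TE library.
#' @param strains character vector of carrier strains (non-empty).
#' @param chrom backbone chromosome name.
#' @param position 0-based insertion point on the backbone.
#' @return one-row data.frame with a comma-separated `strains` column.
#' @export
truth_insertion <- function(te_name, strains, chrom, position) {
  stopifnot(length(strains) >= 1, position >= 0)
  data.frame(te_name = te_name, strains = paste(strains, collapse = ","),
             chrom = chrom, position = as.integer(position),
             stringsAsFactors = FALSE)
}

#' Plant transposon insertions into a backbone genome
#'
#' Builds one genome per strain by inserting full-length TE copies at the
#' designed backbone positions. Each strain receives exactly the insertions
#' whose strain set contains it, so strain genome length equals backbone
#' length plus the summed lengths of its insertions.
#'
#' @param backbone named character vector of backbone chromosomes.
#' @param te_library named character vector of TE consensus sequences.
#' @param design data.frame of insertions as built by [truth_insertion()]
#'   (rbind rows for several insertions).
#' @param strains full strain roster; strains carrying no insertion still
#'   get a (backbone-identical) genome.
#' @return list with `genomes` (named list of per-strain named character
#'   vectors) and `truth` (the design plus a `te_length` column).
#' @export
plant_te_insertions <- function(backbone, te_library, design, strains) {
  stopifnot(is.character(backbone), !is.null(names(backbone)))
  bad_te <- setdiff(design$te_name, names(te_library))
  if (length(bad_te))
    stop("unknown TE name(s): ", paste(bad_te, collapse = ", "), call. = FALSE)
  key <- paste(design$chrom, design$position)
  if (anyDuplicated(key))
    stop("overlapping insertion positions (two insertions at one backbone position)",
         call. = FALSE)
  if (any(design$position > nchar(backbone)[match(design$chrom, names(backbone))]))
    stop("insertion position beyond backbone length", call. = FALSE)
  design$te_length <- nchar(te_library)[match(design$te_name, names(te_library))]
  strain_sets <- strsplit(design$strains, ",", fixed = TRUE)
  genomes <- lapply(strains, function(s) {
    g <- backbone
    for (chrom in names(backbone)) {
      rows <- which(design$chrom == chrom &
                      vapply(strain_sets, function(x) s %in% x, logical(1)))
      if (!length(rows)) next
      rows <- rows[order(design$position[rows], decreasing = TRUE)]
      seqc <- g[[chrom]]
      for (i in rows) {   # back-to-front: earlier coordinates stay valid
        p <- design$position[i]
        seqc <- paste0(substr(seqc, 1L, p), te_library[[design$te_name[i]]],
                       substr(seqc, p + 1L, nchar(seqc)))
      }
      g[[chrom]] <- seqc
    }
    g
  })
  names(genomes) <- strains
  list(genomes = genomes, truth = design)
}

#' Paired-end read simulation settings
#'
#' Defaults emulate a 100+100 nt paired-end resequencing run at 30-fold
#' coverage with a 0.5% per-base substitution error rate.
#'
#' @param read_length read length in nt (>= 20).
#' @param insert_mean mean fragment length (>= 2 * read_length).
#' @param insert_sd fragment length standard deviation.
#' @param coverage fold coverage (> 0).
#' @param error_rate per-base substitution probability, in [0, 0.1).
#' @param seed integer RNG seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(read_length = 100L, insert_mean = 300, insert_sd = 30,
                            coverage = 30, error_rate = 0.005, seed = 1L) {
  if (read_length < 20) stop("'read_length' must be >= 20", call. = FALSE)
  if (insert_mean < 2 * read_length)
    stop("'insert_mean' must be >= 2 * read_length", call. = FALSE)
  if (coverage <= 0) stop("'coverage' must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1)
    stop("'error_rate' must be in [0, 0.1)", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

# Substitution-only error injection, uniform over the three alternatives.
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along the genome with normal lengths
#' truncated at `2 * read_length`; mate 1 is the fragment's 5' end, mate 2
#' the reverse complement of its 3' end (FR orientation). Pair count is
#' `round(coverage * genome_length / (2 * read_length))`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param config a [read_sim_config()].
#' @param id_prefix prefix for read pair identifiers.
#' @return list with `fq1`, `fq2` (data.frames of `id`, `seq`) and `truth`
#'   (pair id, chrom, 0-based fragment start, fragment end).
#' @export
simulate_paired_reads <- function(genome, config = read_sim_config(),
                                  id_prefix = "rd") {
  stopifnot(inherits(config, "read_sim_config"))
  rl <- config$read_length
  lens <- nchar(genome)
  if (any(lens < config$insert_mean + 4 * config$insert_sd))
    stop("genome too short for the configured insert-size distribution",
         call. = FALSE)
  set.seed(config$seed)
  n <- round(config$coverage * sum(lens) / (2 * rl))
  chrom <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
  flen <- pmax(2L * rl, as.integer(round(rnorm(n, config$insert_mean,
                                               config$insert_sd))))
  start0 <- vapply(seq_len(n), function(i) {
    sample.int(lens[[chrom[i]]] - flen[i] + 1L, 1L) - 1L
  }, integer(1))
  frag <- substring(genome[chrom], start0 + 1L, start0 + flen)
  m1 <- substr(frag, 1L, rl)
  m2 <- revcomp(substr(frag, flen - rl + 1L, flen))
  m1 <- inject_errors(m1, config$error_rate)
  m2 <- inject_errors(m2, config$error_rate)
  ids <- sprintf("%s%07d", id_prefix, seq_len(n))
  list(fq1 = data.frame(id = ids, seq = m1, stringsAsFactors = FALSE),
       fq2 = data.frame(id = ids, seq = m2, stringsAsFactors = FALSE),
       truth = data.frame(id = ids, chrom = chrom, start = start0,
                          end = start0 + flen, stringsAsFactors = FALSE))
}

#' Negative-binomial count simulation settings
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per group (two groups).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for per-gene
#'   baseline means.
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion * mu^2.
#' @param planted_de data.frame with columns `gene` (index) and `lfc`
#'   (log2 fold-change of group B over group A), or NULL.
#' @param seed integer RNG seed.
#' @return a `count_sim_config` list.
#' @export
count_sim_config <- function(n_genes = 2000L, n_replicates = 4L,
                             baseline_meanlog = log(100), baseline_sdlog = 1,
                             dispersion = 0.05, planted_de = NULL, seed = 1L) {
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (!is.null(planted_de)) {
    stopifnot(all(c("gene", "lfc") %in% names(planted_de)))
    if (anyDuplicated(planted_de$gene) ||
        any(planted_de$gene < 1) || any(planted_de$gene > n_genes))
      stop("planted gene indices must be unique and in 1..n_genes", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, planted_de = planted_de,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a two-group negative-binomial count matrix
#'
#' @param config a [count_sim_config()].
#' @return list with `counts` (genes x samples integer matrix, columns
#'   `A1..An, B1..Bn`), `groups` (sample group labels), `gene_lengths`
#'   (bp, for FPKM), and `truth` (planted DE table with `gene`, `lfc`,
#'   `direction`).
#' @export
simulate_counts <- function(config = count_sim_config()) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nr <- config$n_replicates
  base <- exp(rnorm(ng, config$baseline_meanlog, config$baseline_sdlog))
  lfc <- numeric(ng)
  if (!is.null(config$planted_de)) lfc[config$planted_de$gene] <- config$planted_de$lfc
  mu <- cbind(matrix(base, ng, nr), matrix(base * 2^lfc, ng, nr))
  counts <- matrix(rnbinom(ng * 2L * nr, mu = mu, size = 1 / config$dispersion),
                   ng, 2L * nr)
  rownames(counts) <- sprintf("gene%05d", seq_len(ng))
  colnames(counts) <- c(paste0("A", seq_len(nr)), paste0("B", seq_len(nr)))
  truth <- if (is.null(config$planted_de)) {
    data.frame(gene = integer(0), lfc = numeric(0), direction = character(0))
  } else {
    data.frame(gene = config$planted_de$gene, lfc = config$planted_de$lfc,
               direction = ifelse(config$planted_de$lfc > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  gene_lengths <- as.integer(round(runif(ng, 500, 5000)))
  names(gene_lengths) <- rownames(counts)
  list(counts = counts, groups = rep(c("A", "B"), each = nr),
       gene_lengths = gene_lengths, truth = truth)
}

#' Simulate marker genotypes for a phenotype-selected mapping population
#'
#' Every segregant in the population carries the causal allele (the
#' population is selected on the expression phenotype); a marker allele
#' comes from the mutant parent with probability `1 - rf`.
#'
#' @param n_segregants number of selected segregants.
#' @param rf_truth named numeric vector of per-marker recombination
#'   fractions, each in [0, 0.5].
#' @param seed integer RNG seed.
#' @param missing_rate per-genotype missing probability.
#' @return list with `genotypes` (long data.frame: segregant, marker,
#'   allele in {mutant-parent, polymorphic-parent, missing}) and
#'   `truth` (marker, rf).
#' @export
simulate_genotypes <- function(n_segregants, rf_truth, seed = 1L,
                               missing_rate = 0) {
  if (any(rf_truth < 0 | rf_truth > 0.5))
    stop("recombination fractions must be in [0, 0.5]", call. = FALSE)
  set.seed(seed)
  segs <- sprintf("seg%04d", seq_len(n_segregants))
  out <- do.call(rbind, lapply(names(rf_truth), function(m) {
    allele <- ifelse(runif(n_segregants) < rf_truth[[m]],
                     "polymorphic-parent", "mutant-parent")
    if (missing_rate > 0)
      allele[runif(n_segregants) < missing_rate] <- "missing"
    data.frame(segregant = segs, marker = m, allele = allele,
               stringsAsFactors = FALSE)
  }))
  list(genotypes = out,
       truth = data.frame(marker = names(rf_truth), rf = unname(rf_truth),
                          stringsAsFactors = FALSE))
}

#' Simulate a ChIP-qPCR Cq table
#'
#' Cq values are generated so that the expected percent-of-input of each
#' region equals the designed enrichment: with perfect doubling,
#' `Cq_IP = Cq_input - log2(percent/100 / input_fraction) + noise`.
#'
#' @param design data.frame with columns `strain`, `mark`, `region`,
#'   `percent_input` (true enrichment, percent).
#' @param n_replicates replicates per design row.
#' @param noise_sd Gaussian Cq noise (cycles).
#' @param input_fraction input DNA fraction the assay is normalized to.
#' @param seed integer RNG seed.
#' @return list with `cq` (strain, mark, region, replicate, Cq_IP,
#'   Cq_input) and `truth` (the design).
#' @export
simulate_cq <- function(design, n_replicates = 6L, noise_sd = 0.1,
                        input_fraction = 0.10, seed = 1L) {
  stopifnot(all(c("strain", "mark", "region", "percent_input") %in% names(design)))
  set.seed(seed)
  rows <- design[rep(seq_len(nrow(design)), each = n_replicates), ]
  rows$replicate <- rep(seq_len(n_replicates), nrow(design))
  rows$Cq_input <- rnorm(nrow(rows), 20, 0.2)
  rows$Cq_IP <- rows$Cq_input -
    log2(rows$percent_input / 100 / input_fraction) +
    rnorm(nrow(rows), 0, noise_sd)
  cq <- rows[, c("strain", "mark", "region", "replicate", "Cq_IP", "Cq_input")]
  rownames(cq) <- NULL
  list(cq = cq, truth = design)
}

#' Simulate a small annotated multi-strain variant table
#'
#' Builds a mixture of shared background variants (alt in every strain),
#' progenitor-private variants, and mutant-specific variants (reference in
#' the progenitor, alt in one or both mutants), with gene and effect
#' annotations.
#'
#' @param strains strain roster; the first entry is the progenitor.
#' @param n_shared,n_progenitor number of background / progenitor-private
#'   variants.
#' @param mutant_specific data.frame with columns `gene`, `effect`,
#'   `strains` (comma-separated carrier mutants), or NULL for a default mix.
#' @param chrom_length backbone length used to draw positions.
#' @param seed integer RNG seed.
#' @return list with `variants` (a VariantRecord data.frame: chrom, pos,
#'   ref, alt, gene, effect, plus one `gt_<strain>` column per strain with
#'   values in {ref, alt, missing}) and `truth` (row class labels).
#' @export
simulate_variants <- function(strains, n_shared = 5L, n_progenitor = 2L,
                              mutant_specific = NULL, chrom_length = 1e6,
                              seed = 1L) {
  stopifnot(length(strains) >= 2)
  progenitor <- strains[1]
  mutants <- strains[-1]
  if (is.null(mutant_specific)) {
    mutant_specific <- data.frame(
      gene = c("geneA", "geneA", "geneB"),
      effect = c("missense_variant", "missense_variant", "synonymous_variant"),
      strains = c(mutants[1], mutants[min(2, length(mutants))], mutants[1]),
      stringsAsFactors = FALSE)
  }
  set.seed(seed)
  n <- n_shared + n_progenitor + nrow(mutant_specific)
  pos <- sort(sample.int(chrom_length, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  cls <- c(rep("shared", n_shared), rep("progenitor_private", n_progenitor),
           rep("mutant_specific", nrow(mutant_specific)))
  gene <- c(sprintf("bg%03d", seq_len(n_shared + n_progenitor)),
            mutant_specific$gene)
  effect <- c(sample(c("synonymous_variant", "intergenic_region"),
                     n_shared + n_progenitor, replace = TRUE),
              mutant_specific$effect)
  gt <- matrix("ref", n, length(strains), dimnames = list(NULL, strains))
  gt[cls == "shared", ] <- "alt"
  gt[cls == "progenitor_private", progenitor] <- "alt"
  ms_rows <- which(cls == "mutant_specific")
  carriers <- strsplit(mutant_specific$strains, ",", fixed = TRUE)
  for (i in seq_along(ms_rows)) gt[ms_rows[i], carriers[[i]]] <- "alt"
  variants <- data.frame(chrom = "chr_1", pos = pos, ref = ref, alt = unname(alt),
                         gene = gene, effect = effect, stringsAsFactors = FALSE)
  for (s in strains) variants[[paste0("gt_", s)]] <- gt[, s]
  list(variants = variants,
       truth = data.frame(pos = pos, class = cls, stringsAsFactors = FALSE))
}
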