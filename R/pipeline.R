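# Orchestration: a seeded end-to-end demonstration run that exercises
# every stage on synthetic data and emits a machine-readable report of
# invariant checks and summary tables. All randomness flows from a single
# root seed expanded per stage.

#' Simulate a protein alignment along a tree
#'
#' Evolves sites independently down a tree: along an edge of length t a
#' site substitutes to a uniformly drawn different residue with
#' probability 1 - exp(-t), which makes the expected Poisson-corrected
#' distance between two taxa approach their path length (up to the
#' finite-alphabet back-substitution bias).
#'
#' @param tree an [ape::phylo] tree with edge lengths.
#' @param n_sites alignment length.
#' @param seed integer RNG seed.
#' @return named character vector of aligned sequences (no gaps).
#' @export
simulate_protein_alignment <- function(tree, n_sites = 500L, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(aa, n_sites, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t_len <- ord$edge.length[e]
    s <- seqs[[parent]]
    mut <- runif(n_sites) < (1 - exp(-t_len))
    if (any(mut))
      s[mut] <- vapply(s[mut], function(x) sample(setdiff(aa, x), 1L),
                       character(1))
    seqs[[child]] <- s
  }
  setNames(vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1)), tree$tip.label)
}

#' Default demonstration configuration
#'
#' A compact stated world: a 60 kb backbone, four strains (progenitor
#' first), two TE families with shared and strain-specific insertions,
#' 20-fold 100+100 nt paired-end coverage at 0.3% error, a 1000-gene
#' count matrix with planted fold-changes, a six-replicate Cq design, a
#' 48-segregant mapping population, and an eight-taxon protein tree.
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    strains = c("cw15arg", "Elow47", "UVM4", "UVM11"),
    genome = list(length = 60000L, gc = 0.64),
    te = list(lengths = c(TOC1_like = 1500L, Gulliver_like = 1000L)),
    reads = list(coverage = 20, error_rate = 0.003, insert_mean = 300,
                 insert_sd = 30),
    survey = list(min_locus_reads = 10L, presence_threshold = 10L,
                  differential_ratio = 10, merge_distance = 200L),
    counts = list(n_genes = 1000L, n_replicates = 4L, dispersion = 0.05,
                  n_de = 30L, lfc = 2),
    chip = list(n_replicates = 6L, noise_sd = 0.1,
                regions = c(CYC6 = 10, YFP_TSS = 2.5, RBCS2 = 10)),
    screen = list(n_segregants = 48L,
                  rf = c(CNA83 = 0.10, PF25 = 0.15, GP221 = 0.5, X1 = 0)),
    phylo = list(n_taxa = 8L, n_sites = 500L, n_bootstrap = 100L)
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; fields override [default_pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config(user$seed %||% 1L)
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

demo_check <- function(checks, name, pass) {
  c(checks, list(list(name = name, pass = isTRUE(pass))))
}

#' Run the end-to-end synthetic demonstration
#'
#' Executes simulate -> map -> TE survey -> variant triage -> DEG -> ChIP
#' -> screen -> phylogeny on seeded synthetic data, writes every summary
#' table as TSV plus a JSON report of invariant checks, and aborts with
#' the stage name on any stage failure.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param out_dir writable output directory (created if absent).
#' @param quiet suppress per-stage log lines.
#' @return the report list, invisibly.
#' @export
run_demo <- function(config = default_pipeline_config(), out_dir,
                     quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  checks <- list()
  strains <- config$strains
  seed <- config$seed

  # --- simulate genomes & plant insertions ------------------------------
  sim <- run_stage("simulate", {
    backbone <- c(chr_1 = simulate_genome(config$genome$length,
                                          config$genome$gc,
                                          seed = child_seed(seed, 1L)))
    te_library <- setNames(lapply(seq_along(config$te$lengths), function(i)
      simulate_genome(config$te$lengths[[i]], 0.5,
                      seed = child_seed(seed, 10L + i))),
      names(config$te$lengths))
    te_library <- unlist(te_library)
    pos <- seq(5000L, config$genome$length - 5000L, length.out = 8L)
    design <- rbind(
      truth_insertion(names(te_library)[1], strains, "chr_1", pos[1]),
      truth_insertion(names(te_library)[1], strains, "chr_1", pos[3]),
      truth_insertion(names(te_library)[2], strains, "chr_1", pos[5]),
      truth_insertion(names(te_library)[1], "UVM11", "chr_1", pos[2]),
      truth_insertion(names(te_library)[2], "UVM4", "chr_1", pos[6]),
      truth_insertion(names(te_library)[1], c("Elow47", "UVM4", "UVM11"),
                      "chr_1", pos[7]))
    planted <- plant_te_insertions(backbone, te_library, design, strains)
    list(backbone = backbone, te_library = te_library, planted = planted)
  })
  log_stage("simulate", "%d strains, %d planted insertions",
            length(strains), nrow(sim$planted$truth))
  lens_ok <- vapply(strains, function(s) {
    carried <- vapply(strsplit(sim$planted$truth$strains, ","),
                      function(x) s %in% x, logical(1))
    nchar(sim$planted$genomes[[s]][["chr_1"]]) ==
      nchar(sim$backbone[["chr_1"]]) + sum(sim$planted$truth$te_length[carried])
  }, logical(1))
  checks <- demo_check(checks, "length_conservation", all(lens_ok))

  # --- reads + TE survey -------------------------------------------------
  survey <- run_stage("te-survey", {
    read_sets <- lapply(seq_along(strains), function(i) {
      cfgr <- read_sim_config(coverage = config$reads$coverage,
                              error_rate = config$reads$error_rate,
                              insert_mean = config$reads$insert_mean,
                              insert_sd = config$reads$insert_sd,
                              seed = child_seed(seed, 20L + i))
      simulate_paired_reads(sim$planted$genomes[[strains[i]]], cfgr,
                            id_prefix = sprintf("s%d_", i))
    })
    names(read_sets) <- strains
    cfg_s <- do.call(survey_config, config$survey)
    run_te_survey(read_sets, sim$te_library, sim$backbone, cfg_s)
  })
  log_stage("te-survey", "%d loci called, %d flagged",
            nrow(survey$loci), sum(survey$loci$flagged))
  truth_pos <- sort(sim$planted$truth$position)
  called_near_truth <- vapply(sim$planted$truth$position, function(p)
    any(survey$loci$start - 300 <= p & survey$loci$end + 300 >= p),
    logical(1))
  checks <- demo_check(checks, "all_planted_insertions_called",
                       all(called_near_truth))
  checks <- demo_check(checks, "row_sum_conservation",
                       all(survey$summary$total ==
                             rowSums(survey$summary[, -(1:2), drop = FALSE])))
  write_tsv(survey$loci, file.path(out_dir, "te_loci.tsv"))
  write_tsv(survey$summary, file.path(out_dir, "te_summary.tsv"))

  # --- variant triage ----------------------------------------------------
  triage <- run_stage("triage", {
    sv <- simulate_variants(strains[-1], seed = child_seed(seed, 30L))
    vcf <- file.path(out_dir, "variants_synthetic.vcf")
    write_vcf(sv$variants, vcf)
    variants <- read_vcf(vcf)
    sel <- select_mutant_specific(variants, "Elow47", c("UVM4", "UVM11"))
    genes <- genes_hit_in_both(sel, "UVM4", "UVM11")
    list(sim = sv, variants = variants, selected = sel, genes = genes)
  })
  log_stage("triage", "%d variants, %d mutant-specific, %d double-hit genes",
            nrow(triage$variants), nrow(triage$selected),
            length(triage$genes))
  checks <- demo_check(checks, "vcf_round_trip",
                       nrow(triage$variants) == nrow(triage$sim$variants))
  checks <- demo_check(
    checks, "triage_matches_truth",
    setequal(triage$selected$pos,
             triage$sim$truth$pos[triage$sim$truth$class == "mutant_specific"]))
  write_tsv(triage$selected, file.path(out_dir, "variants_selected.tsv"))

  # --- DEG ---------------------------------------------------------------
  deg <- run_stage("deg", {
    n_de <- config$counts$n_de
    planted <- data.frame(gene = seq_len(n_de),
                          lfc = rep(c(config$counts$lfc,
                                      -config$counts$lfc),
                                    length.out = n_de))
    cfg_c <- count_sim_config(n_genes = config$counts$n_genes,
                              n_replicates = config$counts$n_replicates,
                              dispersion = config$counts$dispersion,
                              planted_de = planted,
                              seed = child_seed(seed, 40L))
    cs <- simulate_counts(cfg_c)
    stats <- test_de(cs$counts, grep("^A", colnames(cs$counts)),
                     grep("^B", colnames(cs$counts)))
    stats$mean_fpkm <- rowMeans(fpkm(cs$counts, cs$gene_lengths))
    degs <- call_degs(stats, deg_criteria("MA"))
    list(cs = cs, stats = stats, degs = degs)
  })
  log_stage("deg", "%d up / %d down DEGs of %d genes",
            length(deg$degs$up), length(deg$degs$down), nrow(deg$stats))
  ord <- order(deg$stats$pvalue)
  checks <- demo_check(checks, "bh_monotone_in_p",
                       !is.unsorted(deg$stats$padj[ord]))
  write_tsv(deg$stats, file.path(out_dir, "gene_stats.tsv"))

  # --- ChIP --------------------------------------------------------------
  chip <- run_stage("chip", {
    design <- expand.grid(strain = strains[-1], mark = c("H3ac", "H4ac"),
                          region = names(config$chip$regions),
                          stringsAsFactors = FALSE)
    design$percent_input <- config$chip$regions[design$region]
    sc <- simulate_cq(design, n_replicates = config$chip$n_replicates,
                      noise_sd = config$chip$noise_sd,
                      seed = child_seed(seed, 50L))
    enr <- chip_enrichment(sc$cq, reference = "CYC6")
    list(sc = sc, enr = enr)
  })
  ref_rows <- chip$enr$region == "CYC6"
  checks <- demo_check(checks, "reference_normalizes_to_one",
                       all(abs(chip$enr$mean_normalized[ref_rows] - 1) < 1e-12))
  write_tsv(chip$enr, file.path(out_dir, "chip_enrichment.tsv"))
  log_stage("chip", "%d enrichment rows", nrow(chip$enr))

  # --- screen ------------------------------------------------------------
  screen <- run_stage("screen", {
    gt <- simulate_genotypes(config$screen$n_segregants,
                             config$screen$rf,
                             seed = child_seed(seed, 60L))
    rf <- rf_table(gt$genotypes)
    yet <- summarize_complementation(
      data.frame(n_yfp = c(0, 2, 3, 5, 6, 12, 1, 0), n_total = rep(20L, 8)))
    list(gt = gt, rf = rf, yet = yet)
  })
  checks <- demo_check(checks, "absolute_linkage_recovered",
                       screen$rf$rf_percent[screen$rf$marker == "X1"] == 0)
  write_tsv(screen$rf, file.path(out_dir, "rf_table.tsv"))
  write_tsv(screen$yet, file.path(out_dir, "yet_summary.tsv"))
  log_stage("screen", "%d markers, YET<30%% total %.1f%%",
            nrow(screen$rf), screen$yet$total_lt30)

  # --- phylogeny ---------------------------------------------------------
  phylo <- run_stage("phylo", {
    set.seed(child_seed(seed, 70L))
    true_tree <- ape::rtree(config$phylo$n_taxa, rooted = FALSE,
                            br = function(n) runif(n, 0.2, 1))
    aln <- simulate_protein_alignment(true_tree, config$phylo$n_sites,
                                      seed = child_seed(seed, 71L))
    bs <- bootstrap_support(aln, config$phylo$n_bootstrap,
                            seed = child_seed(seed, 72L))
    list(true_tree = true_tree, aln = aln, bs = bs)
  })
  ape::write.tree(phylo$bs$tree, file.path(out_dir, "nj_tree.nwk"))
  checks <- demo_check(checks, "nj_supports_in_range",
                       all(phylo$bs$supports >= 0 & phylo$bs$supports <= 100))
  log_stage("phylo", "tree length %.4f, %d splits supported",
            total_branch_length(phylo$bs$tree), length(phylo$bs$supports))

  report <- list(
    seed = seed,
    checks = checks,
    all_passed = all(vapply(checks, `[[`, logical(1), "pass")),
    tables = list(
      te_summary = survey$summary,
      deg_counts = list(up = length(deg$degs$up), down = length(deg$degs$down)),
      yet = screen$yet,
      rf = screen$rf,
      tree_length = total_branch_length(phylo$bs$tree))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
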