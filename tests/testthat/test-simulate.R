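test_that("simulate_genome honors length, alphabet, determinism and GC", {
  g <- simulate_genome(1000, 0.5, seed = 1)
  expect_equal(nchar(g), 1000)
  expect_true(grepl("^[ACGT]+$", g))
  expect_identical(g, simulate_genome(1000, 0.5, seed = 1))
  # binomial concentration: at n = 1e5 the GC proportion is within 0.01 of
  # the target with overwhelming probability (sd ~ 0.0015)
  big <- simulate_genome(100000, 0.64, seed = 7)
  gc <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.64), 0.01)
  expect_error(simulate_genome(0, 0.5), "length")
  expect_error(simulate_genome(10, 1.2), "gc_fraction")
})

test_that("plant_te_insertions conserves length and places TEs verbatim", {
  backbone <- c(chr_1 = simulate_genome(10000, 0.5, seed = 2))
  te <- c(TE1 = simulate_genome(1000, 0.5, seed = 3),
          TE2 = simulate_genome(400, 0.5, seed = 4))
  strains <- c("s1", "s2", "s3", "s4")
  design <- rbind(truth_insertion("TE1", strains, "chr_1", 2000),
                  truth_insertion("TE2", "s2", "chr_1", 500),
                  truth_insertion("TE1", c("s2", "s3"), "chr_1", 7000))
  res <- plant_te_insertions(backbone, te, design, strains)
  expect_equal(nchar(res$genomes$s1[["chr_1"]]), 11000)
  expect_equal(nchar(res$genomes$s2[["chr_1"]]), 10000 + 1000 + 400 + 1000)
  expect_equal(nchar(res$genomes$s4[["chr_1"]]), 11000)
  # brute-force coordinate lifting: realized position = design position +
  # summed lengths of upstream insertions carried by the strain
  lift <- function(strain, pos) {
    carried <- vapply(strsplit(res$truth$strains, ","),
                      function(x) strain %in% x, logical(1))
    pos + sum(res$truth$te_length[carried & res$truth$position < pos])
  }
  for (i in seq_len(nrow(design))) {
    for (s in strsplit(design$strains[i], ",")[[1]]) {
      at <- lift(s, design$position[i])
      extracted <- substr(res$genomes[[s]][["chr_1"]], at + 1,
                          at + res$truth$te_length[i])
      expect_identical(extracted, unname(te[[design$te_name[i]]]))
    }
  }
  expect_error(plant_te_insertions(backbone, te,
                                   rbind(design, truth_insertion("TE9", "s1", "chr_1", 1)),
                                   strains), "unknown TE")
  expect_error(plant_te_insertions(backbone, te,
                                   rbind(design[1, ], design[1, ]), strains),
               "overlapping")
})

test_that("simulate_paired_reads meets its contracts", {
  genome <- c(chr_1 = simulate_genome(200000, 0.5, seed = 5))
  cfg <- read_sim_config(coverage = 30, error_rate = 0, seed = 9)
  rs <- simulate_paired_reads(genome, cfg)
  # expected-count formula: coverage * L / (2 * rl) = 30000
  expect_lt(abs(nrow(rs$fq1) - 30000) / 30000, 0.05)
  # zero-noise: every read is an exact substring of genome or revcomp
  idx <- sample.int(nrow(rs$fq1), 200)
  both <- paste0(genome[["chr_1"]], "NNN", revcomp(genome[["chr_1"]]))
  expect_true(all(vapply(rs$fq1$seq[idx], grepl, logical(1), x = both,
                         fixed = TRUE)))
  expect_true(all(vapply(rs$fq2$seq[idx], grepl, logical(1), x = both,
                         fixed = TRUE)))
  # mate 2 is the reverse complement of the fragment's far end
  i <- idx[1]
  frag <- substr(genome[["chr_1"]], rs$truth$start[i] + 1, rs$truth$end[i])
  expect_identical(rs$fq2$seq[i],
                   revcomp(substr(frag, nchar(frag) - 99, nchar(frag))))
  # determinism
  rs2 <- simulate_paired_reads(genome, cfg)
  expect_identical(rs$fq1, rs2$fq1)
  expect_identical(rs$fq2, rs2$fq2)
  expect_error(simulate_paired_reads(c(chr_1 = "ACGT"), cfg), "too short")
})

test_that("simulate_counts matches its NB model and determinism", {
  # ratio concentration at n = 400/group: se(ratio) ~ sqrt(2*600/400)/100
  # = 0.017 for NB(100, 0.05), so |ratio - 1| < 0.1 for >= 95% of genes
  cfg <- count_sim_config(n_genes = 500, n_replicates = 400,
                          baseline_meanlog = log(100), baseline_sdlog = 0.5,
                          dispersion = 0.05, seed = 11)
  cs <- simulate_counts(cfg)
  expect_identical(dim(cs$counts), c(500L, 800L))
  ra <- rowMeans(cs$counts[, 1:400]) / pmax(rowMeans(cs$counts[, 401:800]), 1e-9)
  expect_gte(mean(abs(ra - 1) < 0.1), 0.95)
  expect_identical(cs$counts, simulate_counts(cfg)$counts)
  # dispersion -> 0 approaches Poisson: variance ~ mean
  cfg2 <- count_sim_config(n_genes = 200, n_replicates = 200,
                           baseline_meanlog = log(50), baseline_sdlog = 0,
                           dispersion = 1e-6, seed = 12)
  cs2 <- simulate_counts(cfg2)
  vm <- apply(cs2$counts, 1, var) / rowMeans(cs2$counts)
  expect_lt(abs(median(vm) - 1), 0.15)
  expect_error(count_sim_config(dispersion = 0), "dispersion")
  expect_error(count_sim_config(n_genes = 10,
                                planted_de = data.frame(gene = c(1, 1),
                                                        lfc = c(1, 2))),
               "unique")
})

test_that("simulate_genotypes honors the selection model", {
  g0 <- simulate_genotypes(50, c(m = 0), seed = 1)
  expect_true(all(g0$genotypes$allele == "mutant-parent"))
  g5 <- simulate_genotypes(4000, c(m = 0.5), seed = 2)
  expect_lt(abs(mean(g5$genotypes$allele == "polymorphic-parent") - 0.5), 0.03)
  expect_error(simulate_genotypes(10, c(m = 0.6)), "0, 0.5")
})

test_that("simulate_cq encodes the designed enrichment", {
  design <- data.frame(strain = "s", mark = "H3ac",
                       region = c("CYC6", "YFP"), percent_input = c(10, 2.5))
  sc <- simulate_cq(design, n_replicates = 200, noise_sd = 0.05, seed = 3)
  got <- percent_input(sc$cq$Cq_IP, sc$cq$Cq_input)
  expect_lt(abs(mean(got[sc$cq$region == "CYC6"]) - 10), 0.2)
  expect_lt(abs(mean(got[sc$cq$region == "YFP"]) - 2.5), 0.1)
})

test_that("simulate_variants produces the designed genotype patterns", {
  sv <- simulate_variants(c("Elow47", "UVM4", "UVM11"), seed = 4)
  v <- sv$variants
  shared <- sv$truth$class == "shared"
  expect_true(all(v$gt_Elow47[shared] == "alt"))
  ms <- sv$truth$class == "mutant_specific"
  expect_true(all(v$gt_Elow47[ms] == "ref"))
  expect_true(all(v$gt_UVM4[ms] == "alt" | v$gt_UVM11[ms] == "alt"))
  expect_identical(sv$variants, simulate_variants(c("Elow47", "UVM4", "UVM11"),
                                                  seed = 4)$variants)
})
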