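test_that("fpkm matches its closed form", {
  expect_equal(fpkm(matrix(0), 1000, 1e6)[1], 0)
  expect_equal(fpkm(matrix(10), 1000, 1e6)[1], 10)
  expect_equal(fpkm(matrix(5), 500, 2e6)[1], 5)
  m <- matrix(c(10, 20, 30, 40), 2)
  expect_equal(fpkm(m, c(1000, 2000), c(1e6, 2e6)),
               matrix(c(10, 10, 15, 10), 2))
  expect_error(fpkm(m, c(0, 1000)), "lengths")
  expect_error(fpkm(m, c(1000, 2000), c(0, 1)), "totals")
})

test_that("bh_adjust equals the brute-force step-up and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(13)
  for (n in c(1, 2, 10, 1000)) {
    p <- runif(n)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(bh_adjust(c(0.1, 1.4)), "0, 1")
})

test_that("test_de handles null, planted and scaling cases", {
  set.seed(14)
  counts <- matrix(rpois(100 * 8, 50), 100,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  # identical groups: log2FC exactly 0, p = 1
  same <- cbind(counts[, 1:4], counts[, 1:4])
  colnames(same) <- c(paste0("A", 1:4), paste0("B", 1:4))
  st0 <- test_de(same, paste0("A", 1:4), paste0("B", 1:4))
  expect_true(all(st0$log2fc == 0))
  expect_true(all(st0$pvalue == 1))
  # median-of-ratios property: doubling one sample's counts doubles its
  # size factor relative to every other sample (exact), and leaves the
  # test results essentially unchanged (the absolute normalized scale is
  # only identifiable up to a global factor 2^(1/n), which interacts with
  # the pseudocount at ~1e-4 magnitude)
  colnames(counts) <- c(paste0("A", 1:4), paste0("B", 1:4))
  st1 <- test_de(counts, paste0("A", 1:4), paste0("B", 1:4))
  doubled <- counts
  doubled[, "B2"] <- doubled[, "B2"] * 2L
  sf1 <- size_factors(counts)
  sf2 <- size_factors(doubled)
  expect_equal(unname(sf2["B2"] / sf2["A1"]),
               unname(2 * sf1["B2"] / sf1["A1"]), tolerance = 1e-12)
  expect_equal(unname(sf2["A3"] / sf2["A1"]),
               unname(sf1["A3"] / sf1["A1"]), tolerance = 1e-12)
  st2 <- test_de(doubled, paste0("A", 1:4), paste0("B", 1:4))
  expect_equal(st1$log2fc, st2$log2fc, tolerance = 1e-3)
  expect_equal(st1$pvalue, st2$pvalue, tolerance = 1e-3)
  # planted signal: estimated sign correct for >= 99% of planted genes
  planted <- data.frame(gene = 1:100, lfc = rep(c(2, -2), 50))
  cs <- simulate_counts(count_sim_config(n_genes = 1000, n_replicates = 4,
                                         baseline_meanlog = log(100),
                                         baseline_sdlog = 0, dispersion = 0.05,
                                         planted_de = planted, seed = 15))
  st3 <- test_de(cs$counts, 1:4, 5:8)
  expect_gte(mean(sign(st3$log2fc[planted$gene]) == sign(planted$lfc)), 0.99)
  # all-zero genes: log2FC 0, p 1, excluded from the BH n
  cz <- cs$counts
  cz[1:10, ] <- 0L
  stz <- test_de(cz, 1:4, 5:8)
  expect_true(all(stz$log2fc[1:10] == 0 & stz$padj[1:10] == 1))
  expect_equal(bh_adjust(stz$pvalue[!stz$all_zero]), stz$padj[!stz$all_zero])
  expect_error(test_de(counts, "A1", c("B1", "B2")), "2 replicates")
})

test_that("call_degs applies strict thresholds in both modes", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(1.0, 2.5, -3, 0.5),
                   pvalue = c(0.001, 0.001, 0.002, 0.5),
                   padj = c(0.001, 0.005, 0.004, 0.9),
                   mean_fpkm = c(5, 3, 0.5, 2))
  ma <- call_degs(st, deg_criteria("MA"))
  expect_false("a" %in% c(ma$up, ma$down))  # log2FC exactly 1 is not > 1
  expect_setequal(ma$up, "b")
  expect_setequal(ma$down, "c")
  vn <- call_degs(st, deg_criteria("VENN"))
  expect_setequal(vn$up, "b")
  expect_length(vn$down, 0)                 # c fails mean FPKM > 1
  expect_error(call_degs(st[, -5], deg_criteria("VENN")), "mean_fpkm")
  empty <- call_degs(st[0, ], deg_criteria("MA"))
  expect_length(empty$up, 0)
})

test_that("venn_candidates matches per-gene membership brute force", {
  same <- list(c("g1", "g2"))
  v1 <- venn_candidates(same[[1]], same[[1]], same[[1]], same[[1]])
  expect_setequal(v1$candidates, c("g1", "g2"))
  v2 <- venn_candidates("a", "b", "c", "d")
  expect_length(v2$candidates, 0)
  expect_equal(nrow(v2$regions), 15L)
  expect_equal(sum(v2$regions$n), 4L)
  set.seed(16)
  sets <- replicate(4, sample(paste0("g", 1:50), 25), simplify = FALSE)
  v3 <- venn_candidates(sets[[1]], sets[[2]], sets[[3]], sets[[4]])
  oracle <- Filter(function(g) all(vapply(sets, function(s) g %in% s,
                                          logical(1))),
                   paste0("g", 1:50))
  expect_setequal(v3$candidates, oracle)
  expect_equal(sum(v3$regions$n), length(unique(unlist(sets))))
})
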