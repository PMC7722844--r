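make_pair <- function(id, m1_mapped, m2_mapped, te = "TE1") {
  data.frame(id = id, mate = 1:2, seq = c("AAAA", "CCCC"),
             mapped = c(m1_mapped, m2_mapped),
             ref = ifelse(c(m1_mapped, m2_mapped), te, NA),
             pos = ifelse(c(m1_mapped, m2_mapped), 10L, NA),
             strand = ifelse(c(m1_mapped, m2_mapped), "+", NA),
             nm = 0L, stringsAsFactors = FALSE)
}

test_that("classify_half_mapped emits exactly the half-mapped pairs", {
  al <- rbind(make_pair("both", TRUE, TRUE),
              make_pair("none", FALSE, FALSE),
              make_pair("half1", TRUE, FALSE),   # anchor = mate 2
              make_pair("half2", FALSE, TRUE))   # anchor = mate 1
  hm <- classify_half_mapped(al, "strainX")
  expect_setequal(hm$id, c("half1", "half2"))
  expect_identical(hm$anchor_seq[hm$id == "half1"], "CCCC")
  expect_identical(hm$anchor_seq[hm$id == "half2"], "AAAA")
  expect_true(all(hm$te_name == "TE1"))
  expect_error(classify_half_mapped(make_pair("x", TRUE, TRUE)[1, ], "s"),
               "malformed")
  expect_equal(nrow(classify_half_mapped(al[0, ], "s")), 0L)
})

anchors_df <- function(strain, pos, id_prefix = strain, chrom = "chr_1",
                       width = 100L, te = "TE1") {
  data.frame(id = paste0(id_prefix, "_", seq_along(pos)), te_name = te,
             strain = strain, mapped = TRUE, chrom = chrom, pos = as.integer(pos),
             strand = "+", width = width, stringsAsFactors = FALSE)
}

test_that("call_loci merges pileups and applies the pooled 10-read rule", {
  strains <- c("s1", "s2")
  # 12 overlapping anchors -> one locus spanning their union, pooled 12
  a <- anchors_df("s1", seq(1000, 1110, by = 10))
  loci <- call_loci(a, strains)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 1000)
  expect_equal(loci$end, 1110 + 100)
  expect_equal(loci$pooled, 12L)
  # per-base coverage oracle: the called interval is exactly the nonzero-
  # coverage footprint
  cov <- integer(3000)
  for (p in a$pos) cov[(p + 1):(p + 100)] <- cov[(p + 1):(p + 100)] + 1L
  expect_equal(range(which(cov > 0)) - c(1L, 0L), c(loci$start, loci$end))
  # 9 anchors -> below the locus threshold, no locus
  expect_equal(nrow(call_loci(anchors_df("s1", seq(1000, 1080, by = 10)),
                              strains)), 0L)
  expect_equal(nrow(call_loci(a[0, ], strains)), 0L)
  # duplicate read identifiers collapse to distinct reads
  dup <- rbind(a, a)
  expect_equal(call_loci(dup, strains)$pooled, 12L)
  # merging: two 5-read pileups 150 bp apart pool across the gap,
  # and are kept as one 10-read locus
  two <- rbind(anchors_df("s1", seq(1000, 1040, by = 10), "p1"),
               anchors_df("s1", seq(1290, 1330, by = 10), "p2"))
  merged <- call_loci(two, strains)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$pooled, 10L)
  # with merge_distance 0 both pileups fall below min_locus_reads
  expect_equal(nrow(call_loci(two, strains,
                              survey_config(merge_distance = 0L))), 0L)
})

test_that("score_presence applies the inclusive >= 10 boundary", {
  strains <- paste0("s", 1:4)
  loci <- data.frame(chrom = "chr_1", start = 0L, end = 100L, te = "TE1",
                     pooled = 30L, count_s1 = 12L, count_s2 = 3L,
                     count_s3 = 0L, count_s4 = 15L)
  pm <- score_presence(loci, strains)
  expect_identical(unlist(pm[, paste0("present_", strains)], use.names = FALSE),
                   c(TRUE, FALSE, FALSE, TRUE))
  loci[paste0("count_", strains)] <- 10L
  expect_true(all(unlist(score_presence(loci, strains)[, paste0("present_", strains)])))
  # threshold monotonicity: raising the threshold never flips absent -> present
  loci2 <- data.frame(chrom = "chr_1", start = 0L, end = 100L, te = "TE1",
                      pooled = 40L, count_s1 = 9L, count_s2 = 25L,
                      count_s3 = 11L, count_s4 = 0L)
  lo <- score_presence(loci2, strains, survey_config(presence_threshold = 10L))
  hi <- score_presence(loci2, strains, survey_config(presence_threshold = 20L))
  expect_true(all(unlist(hi[, paste0("present_", strains)]) <=
                    unlist(lo[, paste0("present_", strains)])))
})

test_that("flag_differential applies the max/min >= 10 rule with zero-min convention", {
  strains <- paste0("s", 1:4)
  mk <- function(cnt) {
    df <- data.frame(chrom = "chr_1", start = 0L, end = 100L, te = "TE1",
                     pooled = sum(cnt))
    df[paste0("count_", strains)] <- as.list(cnt)
    df
  }
  expect_true(flag_differential(mk(c(100, 5, 80, 90)), strains)$flagged)   # ratio 20
  expect_false(flag_differential(mk(c(20, 15, 18, 19)), strains)$flagged)  # ratio 1.33
  z <- flag_differential(mk(c(10, 0, 0, 0)), strains)
  expect_true(z$flagged)
  expect_identical(z$ratio, Inf)
  # zero minimum but max below the presence threshold: not flagged
  expect_false(flag_differential(mk(c(9, 0, 0, 1)), strains)$flagged)
})

test_that("summarize_survey classifies patterns with row-sum conservation", {
  roster <- c("cw15arg", "Elow47", "UVM4", "UVM11")
  one <- presence_rows("TEx", 1, roster, roster)
  tab1 <- summarize_survey(one, roster)
  expect_equal(tab1$all_strains, 1L)
  expect_equal(tab1$total, 1L)
  expect_equal(sum(unlist(tab1[, -(1:2)])), 1L)
  # an unclassifiable pattern lands in "other"
  odd <- presence_rows("TEx", 2, c("cw15arg", "UVM4"), roster)
  expect_equal(summarize_survey(odd, roster)$other, 2L)
  # zero-presence locus violates the invariant
  bad <- presence_rows("TEx", 1, character(0), roster)
  expect_error(summarize_survey(bad, roster), "zero strains")
})

test_that("raising min_locus_reads never increases the locus count", {
  set.seed(77)
  strains <- c("s1", "s2")
  a <- anchors_df("s1", sample(1:20000, 400, replace = TRUE))
  n_prev <- Inf
  for (thr in c(2L, 5L, 10L, 20L)) {
    n <- nrow(call_loci(a, strains, survey_config(min_locus_reads = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
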