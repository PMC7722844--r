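test_that("build_index stores every k-mer occurrence on both strands", {
  # single reference of length k: forward + reverse complement entries
  idx <- build_index(c(r = "ACGTACGTACGTACG"), k = 15)
  expect_equal(idx$n_entries, 2)
  # palindromic reference of length k: a single entry
  pal <- paste0("ACGTACGA", revcomp("ACGTACGA"))  # 16-mer by construction
  expect_identical(revcomp(pal), pal)
  idxp <- build_index(c(r = pal), k = 16)
  expect_equal(idxp$n_entries, 1)
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(r = "ACGT"), k = 15), "shorter")
  # occurrence counts match a naive string-scan oracle for sampled k-mers
  refs <- mapper_fixture(seed = 7, len = 2000)
  idx2 <- build_index(refs, k = 15)
  set.seed(1)
  for (i in 1:20) {
    r <- sample(names(refs), 1)
    start <- sample(nchar(refs[[r]]) - 14, 1)
    kmer <- substr(refs[[r]], start, start + 14)
    naive <- function(pat) sum(vapply(refs, function(s) {
      length(gregexpr(pat, s, fixed = TRUE)[[1]][
        gregexpr(pat, s, fixed = TRUE)[[1]] > 0])
    }, numeric(1)))
    expected <- naive(kmer) +
      if (revcomp(kmer) == kmer) 0 else naive(revcomp(kmer))
    expect_equal(cpp_index_lookup(idx2$ptr, kmer), expected)
  }
})

test_that("map_read recovers exact and mutated unique substrings", {
  refs <- mapper_fixture(seed = 3)
  idx <- build_index(refs)
  read <- substr(refs[["ctgA"]], 501, 600)
  hit <- map_read(read, idx)
  expect_true(hit$mapped)
  expect_equal(hit$pos, 500)
  expect_identical(hit$strand, "+")
  expect_equal(hit$nm, 0)
  # reverse-complement placement
  hit_rc <- map_read(revcomp(read), idx)
  expect_true(hit_rc$mapped)
  expect_equal(hit_rc$pos, 500)
  expect_identical(hit_rc$strand, "-")
  # no shared k-mer -> unmapped
  set.seed(99)
  junk <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  expect_false(map_read(junk, idx)$mapped)
  expect_error(map_read("ACGTACGT", idx), "shorter")
})

test_that("mapping agrees with the exhaustive Hamming-scan oracle", {
  refs <- mapper_fixture(seed = 11, len = 3000)
  idx <- build_index(refs)
  set.seed(21)
  n_checked <- 0
  for (i in 1:300) {
    r <- sample(names(refs), 1)
    p <- sample(nchar(refs[[r]]) - 100, 1)
    read <- substr(refs[[r]], p, p + 99)
    read <- mutate_read(read, sample(0:4, 1))
    if (runif(1) < 0.5) read <- revcomp(read)
    got <- map_reads(read, idx)
    want <- oracle_map(read, refs)
    expect_identical(got$mapped, want$mapped)
    if (want$mapped) {
      expect_identical(got$ref, want$ref)
      expect_equal(got$pos, want$pos)
      expect_identical(got$strand, want$strand)
      expect_equal(got$nm, want$mm)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 250)  # the vast majority of draws are mappable
})

test_that("map_pairs recovers simulated origins and flags mate mismatches", {
  genome <- c(chr_1 = simulate_genome(50000, 0.5, seed = 31))
  cfg <- read_sim_config(coverage = 4, error_rate = 0, seed = 32)
  rs <- simulate_paired_reads(genome, cfg)
  idx <- build_index(genome)
  pairs <- map_pairs(rs$fq1, rs$fq2, idx)
  m1 <- pairs[pairs$mate == 1L, ]
  ok <- m1$mapped & abs(m1$pos - rs$truth$start) <= 5
  expect_gte(mean(ok), 0.99)
  # mate-2 leftmost coordinate is the fragment end minus the read length
  m2 <- pairs[pairs$mate == 2L, ]
  expect_gte(mean(m2$mapped & abs(m2$pos - (rs$truth$end - 100)) <= 5, na.rm = TRUE),
             0.99)
  # one random mate -> exactly one mapped end
  set.seed(33)
  junk <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  p1 <- data.frame(id = "x", seq = substr(genome[[1]], 1001, 1100))
  p2 <- data.frame(id = "x", seq = junk)
  res <- map_pairs(p1, p2, idx)
  expect_equal(sum(res$mapped), 1L)
  expect_equal(nrow(map_pairs(p1[0, ], p2[0, ], idx)), 0L)
  expect_error(map_pairs(p1, rbind(p2, p2), idx), "record counts")
})

test_that("SAM round-trip preserves every alignment field", {
  genome <- c(chr_1 = simulate_genome(20000, 0.5, seed = 41))
  cfg <- read_sim_config(coverage = 2, error_rate = 0.01, seed = 42)
  rs <- simulate_paired_reads(genome, cfg)
  idx <- build_index(genome)
  pairs <- map_pairs(rs$fq1, rs$fq2, idx)
  # make sure the fixture exercises unmapped records too
  set.seed(43)
  junk <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  extra <- map_pairs(data.frame(id = "junkpair", seq = junk),
                     data.frame(id = "junkpair", seq = substr(genome[[1]], 1, 100)),
                     idx)
  pairs <- rbind(pairs, extra)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(pairs, idx$ref_lengths, path)
  back <- read_sam(path)
  expect_equal(back[order(back$id, back$mate), ],
               pairs[order(pairs$id, pairs$mate), ],
               ignore_attr = TRUE)
  # flags follow the convention (0x1 always; 0x40/0x80 partition the mates)
  lines <- readLines(path)
  flags <- as.integer(vapply(strsplit(lines[!startsWith(lines, "@")], "\t"),
                             `[[`, character(1), 2))
  expect_true(all(bitwAnd(flags, 1L) == 1L))
  expect_equal(sum(bitwAnd(flags, 64L) > 0), sum(bitwAnd(flags, 128L) > 0))
})
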