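# Shared fixtures and independent oracles. Oracles are deliberately
# naive re-implementations, kept independent of the code paths they check.

# Exhaustive Hamming-scan oracle for ungapped mapping: scans every
# placement on every reference and strand; unique strict best under the
# budget wins, ties -> unmapped.
oracle_map <- function(read, refs, max_mm_frac = 0.06) {
  L <- nchar(read)
  max_mm <- floor(max_mm_frac * L)
  rc <- revcomp(read)
  best <- list(mm = L + 1L); second <- L + 1L
  for (r in names(refs)) {
    refc <- strsplit(refs[[r]], "")[[1]]
    if (length(refc) < L) next
    n_pos <- length(refc) - L + 1L
    refmat <- matrix(refc[outer(seq_len(n_pos), 0:(L - 1L), "+")], nrow = n_pos)
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") read else rc, "")[[1]]
      mm <- rowSums(refmat != matrix(q, n_pos, L, byrow = TRUE))
      for (p in seq_len(n_pos)) {
        if (mm[p] < best$mm) {
          second <- best$mm
          best <- list(mm = mm[p], ref = r, pos = p - 1L, strand = strand)
        } else if (mm[p] < second) second <- mm[p]
      }
    }
  }
  if (best$mm > max_mm || best$mm == second) return(list(mapped = FALSE))
  c(list(mapped = TRUE), best)
}

# Brute-force BH by definition: q_i = min over j with p_j >= p_i of
# p_j * n / rank(p_j), evaluated via the sorted step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Inject exactly n_mm substitutions at distinct positions.
mutate_read <- function(seq, n_mm) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_mm)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Small deterministic two-reference fixture for mapper tests.
mapper_fixture <- function(seed = 42, len = 3000) {
  set.seed(seed)
  c(ctgA = simulate_genome(len, 0.5, seed = seed),
    ctgB = simulate_genome(round(len / 2), 0.45, seed = seed + 1))
}

# Truth-presence data.frame in the shape summarize_survey() consumes.
presence_rows <- function(te, n, present, roster) {
  if (n == 0) return(NULL)
  df <- data.frame(te = rep(te, n), stringsAsFactors = FALSE)
  for (s in roster) df[[paste0("present_", s)]] <- s %in% present
  df
}
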