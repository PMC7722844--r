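# The half-mapped-read transposon mobility survey. A read pair with one
# mate aligning to a transposon consensus and the other mate unaligned is
# the signature of a TE/genome junction: the unaligned mate, re-mapped to
# the genome, anchors the element's location. Pileups of anchors pooled
# over strains define candidate loci; per-strain distinct-read counts are
# thresholded into a presence/absence matrix and a differential flag.

#' Survey thresholds
#'
#' All three thresholds default to 10, matching the survey's locus-calling
#' ("regions with at least 10 half-mapped reads"), presence ("present if
#' >= 10 reads") and differential (max/min count ratio >= 10) rules.
#'
#' @param min_locus_reads minimum pooled distinct anchor reads per locus.
#' @param presence_threshold minimum per-strain reads for a present call.
#' @param differential_ratio minimum max/min count ratio to flag a locus.
#' @param merge_distance bp gap below which anchor intervals are merged
#'   (default 200, about two read lengths).
#' @return a `survey_config` list.
#' @export
survey_config <- function(min_locus_reads = 10L, presence_threshold = 10L,
                          differential_ratio = 10, merge_distance = 200L) {
  if (min_locus_reads <= 0 || presence_threshold <= 0 || differential_ratio <= 0)
    stop("all survey thresholds must be positive", call. = FALSE)
  structure(list(min_locus_reads = min_locus_reads,
                 presence_threshold = presence_threshold,
                 differential_ratio = differential_ratio,
                 merge_distance = as.integer(merge_distance)),
            class = "survey_config")
}

#' Isolate half-mapped read pairs
#'
#' Filters paired alignments against a TE reference set down to pairs with
#' exactly one TE-mapped and one TE-unmapped mate. The unmapped mate
#' becomes the anchor read.
#'
#' @param alignments data.frame from [map_pairs()] (reads mapped against
#'   the TE consensus set).
#' @param strain strain label attached to every emitted anchor.
#' @return data.frame with columns `id`, `te_name` (reference the mapped
#'   mate hit), `anchor_seq`, `strain`.
#' @export
classify_half_mapped <- function(alignments, strain) {
  if (nrow(alignments) == 0L)
    return(data.frame(id = character(0), te_name = character(0),
                      anchor_seq = character(0), strain = character(0)))
  n_mates <- table(alignments$id)
  if (any(n_mates != 2L))
    stop("malformed pairs: every identifier needs exactly two mates",
         call. = FALSE)
  a <- alignments[order(match(alignments$id, unique(alignments$id)),
                        alignments$mate), ]
  m1 <- a[a$mate == 1L, ]; m2 <- a[a$mate == 2L, ]
  half <- xor(m1$mapped, m2$mapped)
  mapped_mate <- ifelse(m1$mapped[half], 1L, 2L)
  data.frame(
    id = m1$id[half],
    te_name = ifelse(mapped_mate == 1L, m1$ref[half], m2$ref[half]),
    anchor_seq = ifelse(mapped_mate == 1L, m2$seq[half], m1$seq[half]),
    strain = strain, stringsAsFactors = FALSE)
}

#' Map anchor reads to the genome
#'
#' @param half_mapped data.frame from [classify_half_mapped()] (rows from
#'   several strains may be concatenated).
#' @param genome_index [build_index()] over the genome assembly.
#' @param max_mismatch_fraction mapper mismatch budget.
#' @return data.frame of anchors with genomic coordinates: `id`,
#'   `te_name`, `strain`, `mapped`, `chrom`, `pos` (0-based), `strand`,
#'   `width`.
#' @export
anchor_map <- function(half_mapped, genome_index, max_mismatch_fraction = 0.06) {
  if (nrow(half_mapped) == 0L)
    return(data.frame(id = character(0), te_name = character(0),
                      strain = character(0), mapped = logical(0),
                      chrom = character(0), pos = integer(0),
                      strand = character(0), width = integer(0)))
  m <- map_reads(half_mapped$anchor_seq, genome_index, max_mismatch_fraction,
                 ids = half_mapped$id)
  data.frame(id = half_mapped$id, te_name = half_mapped$te_name,
             strain = half_mapped$strain, mapped = m$mapped,
             chrom = m$ref, pos = m$pos, strand = m$strand,
             width = nchar(half_mapped$anchor_seq), stringsAsFactors = FALSE)
}

#' Call transposon loci from pooled anchor coverage
#'
#' Loci are maximal intervals of nonzero anchor coverage pooled over all
#' strains, after merging intervals separated by at most `merge_distance`,
#' retaining intervals supported by at least `min_locus_reads` distinct
#' anchor reads. Per-strain distinct-read counts are attached.
#'
#' @param anchored data.frame from [anchor_map()]; unmapped rows are
#'   ignored.
#' @param strains strain roster (fixes the count column order).
#' @param config a [survey_config()].
#' @return data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end` (0-based half-open), `te`, `pooled`, and one
#'   `count_<strain>` column per strain.
#' @export
call_loci <- function(anchored, strains, config = survey_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), te = character(0), pooled = integer(0))
  for (s in strains) empty[[paste0("count_", s)]] <- integer(0)
  a <- anchored[anchored$mapped, , drop = FALSE]
  a <- a[!duplicated(paste(a$strain, a$id)), , drop = FALSE]  # distinct reads
  if (nrow(a) == 0L) return(empty)
  out <- lapply(sort(unique(a$chrom)), function(ch) {
    ac <- a[a$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = ac$pos + 1L, width = ac$width)
    red <- IRanges::reduce(ir, min.gapwidth = config$merge_distance + 1L)
    hits <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hits)
    anchor_row <- S4Vectors::queryHits(hits)
    loci <- data.frame(chrom = ch, start = IRanges::start(red) - 1L,
                       end = IRanges::end(red), stringsAsFactors = FALSE)
    loci$te <- vapply(seq_along(red), function(i) {
      paste(sort(unique(ac$te_name[anchor_row[grp == i]])), collapse = ",")
    }, character(1))
    loci$pooled <- as.integer(tabulate(grp, nbins = length(red)))
    for (s in strains) {
      in_s <- ac$strain[anchor_row] == s
      loci[[paste0("count_", s)]] <-
        as.integer(tabulate(grp[in_s], nbins = length(red)))
    }
    loci
  })
  out <- do.call(rbind, out)
  out <- out[out$pooled >= config$min_locus_reads, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score per-strain presence calls
#'
#' A transposon at a locus is present in a strain when at least
#' `presence_threshold` distinct reads from that strain map to it
#' (inclusive boundary).
#'
#' @param loci data.frame from [call_loci()].
#' @param strains strain roster.
#' @param config a [survey_config()].
#' @return `loci` with one logical `present_<strain>` column per strain.
#' @export
score_presence <- function(loci, strains, config = survey_config()) {
  for (s in strains) {
    cc <- loci[[paste0("count_", s)]]
    if (is.null(cc)) stop("missing count column for strain ", s, call. = FALSE)
    loci[[paste0("present_", s)]] <- cc >= config$presence_threshold
  }
  loci
}

#' Flag differential loci
#'
#' Computes the max/min per-strain count ratio per locus and flags loci at
#' ratio >= `differential_ratio`. A zero minimum counts as an infinite
#' ratio and is flagged whenever the maximum reaches the presence
#' threshold (a locus robustly covered in one strain and absent in another
#' is precisely a candidate transposition).
#'
#' @param loci data.frame from [call_loci()].
#' @param strains strain roster.
#' @param config a [survey_config()].
#' @return `loci` with `ratio` (Inf for zero minima) and logical `flagged`
#'   columns.
#' @export
flag_differential <- function(loci, strains, config = survey_config()) {
  cnt <- as.matrix(loci[, paste0("count_", strains), drop = FALSE])
  mx <- apply(cnt, 1L, max)
  mn <- apply(cnt, 1L, min)
  loci$ratio <- ifelse(mn == 0, Inf, mx / mn)
  loci$flagged <- ifelse(mn == 0, mx >= config$presence_threshold,
                         mx / mn >= config$differential_ratio)
  if (nrow(loci) == 0L) {
    loci$ratio <- numeric(0); loci$flagged <- logical(0)
  }
  loci
}

#' Summarize the survey as a per-TE pattern table
#'
#' Assigns every locus to exactly one presence-pattern class: present in
#' all strains, present in one strain only (one class per strain), present
#' in all strains except the first of the roster (the
#' shared-by-derived-strains class), or an explicit "other" class. Row
#' sums are conserved: a TE's total equals the sum of its class counts.
#'
#' @param presence data.frame with a `te` column and one logical
#'   `present_<strain>` column per roster strain (e.g. from
#'   [score_presence()]); every locus must be present in at least one
#'   strain.
#' @param roster strain roster; the first strain is the reference
#'   progenitor excluded from the shared-derived class.
#' @return data.frame with columns `te`, `total`, `all_strains`,
#'   `only_<strain>` per strain, `derived_shared`, `other`.
#' @export
summarize_survey <- function(presence, roster) {
  pm <- as.matrix(presence[, paste0("present_", roster), drop = FALSE])
  if (any(rowSums(pm) == 0))
    stop("locus present in zero strains violates the locus invariant",
         call. = FALSE)
  n <- length(roster)
  class_of <- apply(pm, 1L, function(p) {
    if (all(p)) return("all_strains")
    if (sum(p) == 1L) return(paste0("only_", roster[which(p)]))
    if (!p[1L] && all(p[-1L])) return("derived_shared")
    "other"
  })
  classes <- c("all_strains", paste0("only_", roster), "derived_shared", "other")
  tes <- sort(unique(presence$te))
  out <- data.frame(te = tes, total = 0L, stringsAsFactors = FALSE)
  for (cl in classes) out[[cl]] <- 0L
  for (i in seq_along(tes)) {
    tab <- table(factor(class_of[presence$te == tes[i]], levels = classes))
    out[i, classes] <- as.integer(tab)
    out$total[i] <- sum(tab)
  }
  stopifnot(all(out$total == rowSums(out[, classes, drop = FALSE])))
  out
}

#' Run the whole survey on per-strain read sets
#'
#' Convenience wrapper: classify half-mapped pairs against the TE set,
#' anchor the unmapped mates on the genome, call loci, score presence, and
#' flag differential loci.
#'
#' @param read_sets named list (one entry per strain) of lists with `fq1`
#'   and `fq2` data.frames.
#' @param te_library named character vector of TE consensus sequences.
#' @param genome named character vector of genome chromosomes.
#' @param config a [survey_config()].
#' @param max_mismatch_fraction mapper mismatch budget.
#' @return list with `loci` (scored and flagged), `summary` (per-TE
#'   pattern table) and `anchors`.
#' @export
run_te_survey <- function(read_sets, te_library, genome,
                          config = survey_config(),
                          max_mismatch_fraction = 0.06) {
  strains <- names(read_sets)
  te_index <- build_index(te_library)
  genome_index <- build_index(genome)
  anchors <- do.call(rbind, lapply(strains, function(s) {
    pairs <- map_pairs(read_sets[[s]]$fq1, read_sets[[s]]$fq2, te_index,
                       max_mismatch_fraction)
    anchor_map(classify_half_mapped(pairs, s), genome_index,
               max_mismatch_fraction)
  }))
  loci <- call_loci(anchors, strains, config)
  loci <- score_presence(loci, strains, config)
  loci <- flag_differential(loci, strains, config)
  summary <- if (nrow(loci)) summarize_survey(loci, strains) else
    data.frame(te = character(0), total = integer(0))
  list(loci = loci, summary = summary, anchors = anchors)
}
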