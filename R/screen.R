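# Genetics of the expression screen: phenotype calls on transformant
# counts, recombination-frequency estimation on a phenotype-selected
# mapping population, linkage calls, and YET (YFP Expressing
# Transformants) complementation scoring.
#
# Threshold asymmetry is intentional and follows the printed rules: the
# expression phenotype is called at >= 30% YFP-positive transformants
# (inclusive), complementation at YET < 30% (strict).

#' Call the transgene expression phenotype
#'
#' TRUE when at least `threshold` of the analyzed colonies show clearly
#' visible YFP fluorescence (inclusive boundary: 6 of 20 is positive).
#'
#' @param n_yfp YFP-expressing colony count.
#' @param n_total total colonies analyzed (>= 1).
#' @param threshold phenotype proportion (default 0.30).
#' @return logical (vectorized).
#' @export
score_expression_phenotype <- function(n_yfp, n_total, threshold = 0.30) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1", call. = FALSE)
  if (any(n_yfp < 0 | n_yfp > n_total))
    stop("'n_yfp' must be in 0..n_total", call. = FALSE)
  n_yfp / n_total >= threshold
}

#' Recombination frequency on a phenotype-selected population
#'
#' All scored segregants carry the causal allele; RF% is the percentage of
#' scored segregants whose marker allele comes from the polymorphic
#' (non-mutant) parent. Missing genotypes are excluded from the
#' denominator. This is a one-sided estimate on a selected population; no
#' map-distance conversion is applied.
#'
#' @param alleles character vector of allele origins for one marker, in
#'   {"mutant-parent", "polymorphic-parent", "missing"}.
#' @return list with `rf_percent` (1 decimal, half away from zero),
#'   `n_recombinant`, `n_scored`.
#' @export
recombination_frequency <- function(alleles) {
  scored <- alleles[alleles != "missing"]
  if (!length(scored)) stop("zero scored segregants", call. = FALSE)
  n_rec <- sum(scored == "polymorphic-parent")
  list(rf_percent = round_half_up(100 * n_rec / length(scored), 1),
       n_recombinant = n_rec, n_scored = length(scored))
}

#' Recombination frequencies for a genotype table
#'
#' @param genotypes long data.frame (`segregant`, `marker`, `allele`) as
#'   produced by [simulate_genotypes()].
#' @return data.frame with `marker`, `rf_percent`, `n_recombinant`,
#'   `n_scored`, `linked`.
#' @export
rf_table <- function(genotypes) {
  markers <- unique(genotypes$marker)
  out <- do.call(rbind, lapply(markers, function(m) {
    rf <- recombination_frequency(genotypes$allele[genotypes$marker == m])
    data.frame(marker = m, rf_percent = rf$rf_percent,
               n_recombinant = rf$n_recombinant, n_scored = rf$n_scored,
               stringsAsFactors = FALSE)
  }))
  out$linked <- call_linkage(out$rf_percent)
  out
}

#' Linkage call from a recombination frequency
#'
#' Linked iff RF is strictly below the threshold (default 20%).
#'
#' @param rf_percent recombination frequency in percent, in [0, 100].
#' @param threshold linkage threshold in percent (default 20).
#' @return logical (vectorized).
#' @export
call_linkage <- function(rf_percent, threshold = 20) {
  if (any(rf_percent < 0 | rf_percent > 100))
    stop("'rf_percent' must be in [0, 100]", call. = FALSE)
  rf_percent < threshold
}

yet_classes <- c("0", "1-10", "11-20", "21-29", ">=30")

#' YET score and complementation class for one line
#'
#' YET = 100 * n_yfp / n_total, rounded half away from zero to 1 decimal.
#' Classes are the printed contiguous integer bins applied to the rounded
#' percentage (a line at exactly 10.0 falls in "1-10"); a line is
#' complemented iff its YET is below 30.
#'
#' @param n_yfp YFP-expressing supertransformant count.
#' @param n_total total supertransformants analyzed (>= 1).
#' @return data.frame with `yet_percent`, `class`, `complemented`.
#' @export
yet_score <- function(n_yfp, n_total) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1", call. = FALSE)
  if (any(n_yfp < 0 | n_yfp > n_total))
    stop("'n_yfp' must be in 0..n_total", call. = FALSE)
  yet <- round_half_up(100 * n_yfp / n_total, 1)
  cls <- ifelse(yet == 0, "0",
                ifelse(yet <= 10, "1-10",
                       ifelse(yet <= 20, "11-20",
                              ifelse(yet < 30, "21-29", ">=30"))))
  data.frame(yet_percent = yet, class = factor(cls, levels = yet_classes),
             complemented = yet < 30)
}

#' Summarize a complementation screen (one construct/strain)
#'
#' Produces the standard complementation row: the percentage of lines in
#' each of the four complementation classes (YET = 0, 1-10, 11-20, 21-29)
#' plus the total complementation efficiency (YET < 30), all to 1 decimal.
#' The total equals the sum of the four class counts divided by the line
#' count — checked exactly on counts.
#'
#' @param screens data.frame with columns `n_yfp` and `n_total`, one row
#'   per line.
#' @return one-row data.frame: `n_lines`, `total_lt30` (percent),
#'   `pct_0`, `pct_1_10`, `pct_11_20`, `pct_21_29`, `pct_ge30`.
#' @export
summarize_complementation <- function(screens) {
  stopifnot(nrow(screens) >= 1)
  ys <- yet_score(screens$n_yfp, screens$n_total)
  cnt <- table(ys$class)
  n <- nrow(screens)
  stopifnot(sum(cnt[yet_classes[1:4]]) == sum(ys$complemented))
  pct <- round_half_up(100 * as.numeric(cnt) / n, 1)
  data.frame(n_lines = n,
             total_lt30 = round_half_up(100 * sum(ys$complemented) / n, 1),
             pct_0 = pct[1], pct_1_10 = pct[2], pct_11_20 = pct[3],
             pct_21_29 = pct[4], pct_ge30 = pct[5])
}
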