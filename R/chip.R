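# ChIP-qPCR quantification: percent-of-input from Cq differences and
# normalization to a reference region (the CYC6 promoter for euchromatic
# marks, a telomere-flanking region for H3K9me1).

#' Percent-of-input from a Cq pair
#'
#' percent = 100 * input_fraction * efficiency^(Cq_input - Cq_IP). With
#' perfect doubling (efficiency 2) and a 10% input, equal Cq values give
#' exactly 10%.
#'
#' @param cq_ip IP-sample Cq (> 0).
#' @param cq_input input-sample Cq (> 0).
#' @param input_fraction input DNA fraction, in (0, 1] (default 0.10).
#' @param efficiency amplification base per cycle, in (1, 2] (default 2).
#' @return percent of input (vectorized).
#' @export
percent_input <- function(cq_ip, cq_input, input_fraction = 0.10,
                          efficiency = 2) {
  if (any(cq_ip <= 0) || any(cq_input <= 0))
    stop("Cq values must be > 0", call. = FALSE)
  if (input_fraction <= 0 || input_fraction > 1)
    stop("'input_fraction' must be in (0, 1]", call. = FALSE)
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must be in (1, 2]", call. = FALSE)
  100 * input_fraction * efficiency^(cq_input - cq_ip)
}

#' Normalize enrichments to a reference region
#'
#' Divides each region's value by the reference region's value; the
#' reference maps to exactly 1.
#'
#' @param values named numeric vector of percent-input values per region.
#' @param reference reference region name present in `values`.
#' @return named numeric vector of normalized values.
#' @export
normalize_to_reference <- function(values, reference) {
  if (!reference %in% names(values))
    stop("reference region '", reference, "' missing", call. = FALSE)
  if (values[[reference]] <= 0)
    stop("reference region has non-positive signal", call. = FALSE)
  values / values[[reference]]
}

#' Full ChIP-qPCR enrichment table from a Cq table
#'
#' Per replicate: percent-of-input per region, then division by the
#' reference region (replicate-wise normalization); replicates are then
#' aggregated as mean with SD and SE.
#'
#' @param cq data.frame with columns `strain`, `mark`, `region`,
#'   `replicate`, `Cq_IP`, `Cq_input`.
#' @param reference reference region id (e.g. "CYC6").
#' @param input_fraction,efficiency see [percent_input()].
#' @return data.frame with `strain`, `mark`, `region`, `mean_percent_input`,
#'   `mean_normalized`, `sd_normalized`, `se_normalized`, `n_replicates`.
#' @export
chip_enrichment <- function(cq, reference, input_fraction = 0.10,
                            efficiency = 2) {
  cq$percent <- percent_input(cq$Cq_IP, cq$Cq_input, input_fraction, efficiency)
  cq$norm <- NA_real_
  for (key in unique(paste(cq$strain, cq$mark, cq$replicate, sep = "\r"))) {
    idx <- paste(cq$strain, cq$mark, cq$replicate, sep = "\r") == key
    vals <- setNames(cq$percent[idx], cq$region[idx])
    cq$norm[idx] <- unname(normalize_to_reference(vals, reference)[cq$region[idx]])
  }
  agg <- unique(cq[, c("strain", "mark", "region")])
  rownames(agg) <- NULL
  stats <- lapply(seq_len(nrow(agg)), function(i) {
    idx <- cq$strain == agg$strain[i] & cq$mark == agg$mark[i] &
      cq$region == agg$region[i]
    v <- cq$norm[idx]
    c(mean_percent_input = mean(cq$percent[idx]), mean_normalized = mean(v),
      sd_normalized = sd(v), se_normalized = sd(v) / sqrt(length(v)),
      n_replicates = length(v))
  })
  cbind(agg, do.call(rbind, stats))
}
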