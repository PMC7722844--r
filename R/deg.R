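# Differential-expression stage for gene-level count matrices. The
# per-gene test is a declared stand-in for heavier count-model inference:
# median-of-ratios library-size normalization, a two-sided Welch test on
# log2(normalized count + c), Benjamini-Hochberg adjustment, and the two
# printed DEG criteria (MA: |log2FC| > 1 and padj < 0.01; VENN: fold
# change > 2, mean FPKM > 1, padj < 0.01 — all strict inequalities).

#' FPKM from counts, gene lengths and library totals
#'
#' FPKM = count / (length/1000) / (total/1e6): fragments per kilobase of
#' gene per million assigned fragments.
#'
#' @param counts genes x samples numeric matrix.
#' @param gene_lengths per-gene lengths in bp (> 0), recycled across
#'   samples.
#' @param totals per-sample assigned-fragment totals (> 0); defaults to
#'   the column sums.
#' @return FPKM matrix with the dimensions of `counts`.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(totals <= 0)) stop("library totals must be > 0", call. = FALSE)
  sweep(counts / (gene_lengths / 1000), 2L, totals / 1e6, "/")
}

#' Median-of-ratios library size factors
#'
#' Per-sample factors against the geometric-mean pseudo-reference; genes
#' with a zero count in any sample are excluded from factor estimation.
#'
#' @param counts genes x samples numeric matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep))
    stop("no gene without zeros: cannot estimate size factors", call. = FALSE)
  logg <- rowMeans(log(counts[keep, , drop = FALSE]))
  apply(counts[keep, , drop = FALSE], 2L,
        function(cc) exp(median(log(cc) - logg)))
}

# Empirical-Bayes variance moderation toward a mean-variance trend
# (method-of-moments on log sample variances; Smyth-style F prior).
# s2 are per-gene pooled residual variances on d residual df; covariate is
# the per-gene average log2 expression the prior trend is fitted against.
moderate_variances <- function(s2, d, covariate) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 10L)  # too few informative genes: no moderation
    return(list(s2_post = s2, df_prior = 0))
  z <- log(s2[ok])
  trend <- rep(mean(z), length(z))
  if (length(unique(covariate[ok])) > 10L) {
    lo <- lowess(covariate[ok], z, f = 0.5)
    trend <- approx(lo$x, lo$y, xout = covariate[ok], rule = 2)$y
  }
  bias <- digamma(d / 2) - log(d / 2)      # E[log s2] - log sigma2
  resid_var <- var(z - trend)
  excess <- resid_var - trigamma(d / 2)
  df_prior <- if (is.na(excess) || excess <= 0) Inf else {
    # invert trigamma(d0/2) = excess
    2 * uniroot(function(x) trigamma(x) - excess, c(1e-8, 1e8),
                tol = 1e-10)$root
  }
  s0 <- exp(trend - bias)
  s2_post <- s2
  if (is.infinite(df_prior)) {
    s2_post[ok] <- s0
  } else {
    s2_post[ok] <- (df_prior * s0 + d * s2[ok]) / (df_prior + d)
  }
  s2_post[!ok] <- if (is.infinite(df_prior)) mean(s0) else
    df_prior * mean(s0) / (df_prior + d)   # zero-variance genes get the prior
  list(s2_post = s2_post, df_prior = df_prior)
}

#' Per-gene differential test (stand-in)
#'
#' log2 fold-change is computed on library-size-normalized means with
#' pseudocount `c`; the p-value comes from a two-sided moderated t-test on
#' log2(normalized count + c): per-gene pooled variances are shrunk toward
#' a fitted mean-variance trend with an empirical-Bayes F prior, which at
#' typical replicate counts (n = 3-4 per group) is what makes strict
#' adjusted-p thresholds attainable. Genes with zero counts in all samples
#' are reported with log2FC 0 and p 1 and are excluded from the BH n.
#'
#' @param counts genes x samples numeric matrix.
#' @param group_a,group_b column names or indices of the two groups
#'   (at least 2 replicates each).
#' @param pseudocount additive constant c (default 0.5).
#' @param moderate shrink variances toward the trend (default TRUE; FALSE
#'   gives the plain Welch test).
#' @return data.frame with `gene`, `log2fc` (B over A), `pvalue`, `padj`,
#'   `all_zero`.
#' @export
test_de <- function(counts, group_a, group_b, pseudocount = 0.5,
                    moderate = TRUE) {
  counts <- as.matrix(counts)
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 replicates", call. = FALSE)
  sf <- size_factors(counts[, c(colnames(a), colnames(b)), drop = FALSE])
  na <- sweep(a, 2L, sf[seq_len(ncol(a))], "/")
  nb <- sweep(b, 2L, sf[ncol(a) + seq_len(ncol(b))], "/")
  log2fc <- log2((rowMeans(nb) + pseudocount) / (rowMeans(na) + pseudocount))
  la <- log2(na + pseudocount); lb <- log2(nb + pseudocount)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, var); vb <- apply(lb, 1L, var)
  d <- ncol(a) + ncol(b) - 2L
  s2 <- ((ncol(a) - 1) * va + (ncol(b) - 1) * vb) / d
  if (moderate) {
    mod <- moderate_variances(s2, d, covariate = (ma + mb) / 2)
    s2_use <- mod$s2_post
    df <- d + min(mod$df_prior, 1e6)
  } else {
    s2_use <- s2
    df <- d
  }
  se2 <- s2_use * (1 / ncol(a) + 1 / ncol(b))
  tstat <- (mb - ma) / sqrt(se2)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance genes: p = 1 when the difference is also zero
  degen <- !is.finite(p)
  p[degen] <- ifelse(abs(mb - ma)[degen] < 1e-12, 1, 0)
  all_zero <- rowSums(counts[, c(colnames(a), colnames(b)), drop = FALSE]) == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  padj <- rep(NA_real_, length(p))
  padj[!all_zero] <- bh_adjust(p[!all_zero])
  padj[all_zero] <- 1
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             log2fc = unname(log2fc), pvalue = unname(p),
             padj = unname(padj), all_zero = unname(all_zero),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: sort p ascending, q_(i) = min_{j >= i} p_(j) * n / j,
#' capped at 1, original order restored.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' DEG criteria
#'
#' Two modes, both with strict inequalities exactly as printed: `MA`
#' (|log2FC| > lfc and padj < alpha) and `VENN` (fold change > fc, mean
#' FPKM across all samples > min_fpkm, padj < alpha).
#'
#' @param mode "MA" or "VENN".
#' @param lfc log2 fold-change threshold for MA mode (default 1).
#' @param fc fold-change threshold for VENN mode (default 2).
#' @param min_fpkm mean-FPKM threshold for VENN mode (default 1).
#' @param alpha adjusted-p threshold (default 0.01).
#' @return a `deg_criteria` list.
#' @export
deg_criteria <- function(mode = c("MA", "VENN"), lfc = 1, fc = 2,
                         min_fpkm = 1, alpha = 0.01) {
  structure(list(mode = match.arg(mode), lfc = lfc, fc = fc,
                 min_fpkm = min_fpkm, alpha = alpha),
            class = "deg_criteria")
}

#' Call directional DEG sets
#'
#' @param stats data.frame from [test_de()]; for VENN mode it must also
#'   carry a `mean_fpkm` column (mean FPKM across all samples).
#' @param criteria a [deg_criteria()].
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(stats, criteria = deg_criteria()) {
  if (nrow(stats) == 0L) return(list(up = character(0), down = character(0)))
  if (criteria$mode == "MA") {
    hit <- abs(stats$log2fc) > criteria$lfc & stats$padj < criteria$alpha
  } else {
    if (is.null(stats$mean_fpkm))
      stop("VENN mode requires a 'mean_fpkm' column", call. = FALSE)
    hit <- 2^abs(stats$log2fc) > criteria$fc &
      stats$mean_fpkm > criteria$min_fpkm & stats$padj < criteria$alpha
  }
  hit[is.na(hit)] <- FALSE
  list(up = stats$gene[hit & stats$log2fc > 0],
       down = stats$gene[hit & stats$log2fc < 0])
}

#' Four-way directional Venn candidate set
#'
#' Intersects the four DEG sets of the candidate-gene logic (up in mutant
#' 1 vs control, up in mutant 2 vs control, down in complemented 1 vs
#' mutant, down in complemented 2 vs mutant) and reports all 15 region
#' cardinalities of the 4-set Venn decomposition.
#'
#' @param up_m1,up_m2,down_c1,down_c2 character vectors (gene sets).
#' @return list with `candidates` (the 4-way intersection, sorted) and
#'   `regions` (data.frame of the 15 exclusive region cardinalities,
#'   membership flagged per set).
#' @export
venn_candidates <- function(up_m1, up_m2, down_c1, down_c2) {
  sets <- list(up_m1 = unique(up_m1), up_m2 = unique(up_m2),
               down_c1 = unique(down_c1), down_c2 = unique(down_c2))
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(up_m1 = c(FALSE, TRUE), up_m2 = c(FALSE, TRUE),
                        down_c1 = c(FALSE, TRUE), down_c2 = c(FALSE, TRUE))
  combos <- combos[rowSums(combos) > 0L, ]
  combos$n <- apply(combos, 1L, function(f) {
    if (length(all_genes) == 0L) return(0L)
    sum(apply(memb, 1L, function(m) all(m == f)))
  })
  rownames(combos) <- NULL
  list(candidates = sort(all_genes[rowSums(memb) == 4L]),
       regions = combos)
}
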