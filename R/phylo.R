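# Poisson-corrected protein distances, neighbor-joining, bootstrap
# supports. Distances: d = -ln(1 - p) with p the proportion of differing
# comparable (non-gap) sites; NJ is the standard Saitou-Nei agglomeration
# with deterministic lowest-(row, column) tie-breaking. Trees are ape
# "phylo" objects.

GAP_CHARS <- c("-", ".")

aln_matrix <- function(alignment) {
  if (length(alignment) < 2) stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Poisson-corrected distance between two aligned sequences
#'
#' p = differing comparable sites / comparable sites; d = -ln(1 - p).
#' Saturated pairs (p >= 1) and pairs with zero comparable sites are
#' errors.
#'
#' @param seq_i,seq_j aligned sequences of equal length.
#' @param gap_mode "complete" drops every column holding a gap in either
#'   sequence context supplied here (for a pair the two modes coincide);
#'   kept for interface symmetry with [poisson_dist_matrix()].
#' @return the distance (non-negative scalar).
#' @export
poisson_distance <- function(seq_i, seq_j, gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  m <- aln_matrix(c(a = seq_i, b = seq_j))
  ok <- !(m[1, ] %in% GAP_CHARS) & !(m[2, ] %in% GAP_CHARS)
  if (!any(ok)) stop("zero comparable sites", call. = FALSE)
  p <- mean(m[1, ok] != m[2, ok])
  if (p >= 1) stop("saturated distance (p >= 1)", call. = FALSE)
  -log(1 - p)
}

#' Poisson-corrected distance matrix for an alignment
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @param gap_mode "complete" (default): drop all columns containing a gap
#'   in any sequence before any comparison; "pairwise": drop gapped
#'   columns per pair.
#' @return symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @export
poisson_dist_matrix <- function(alignment, gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  m <- aln_matrix(alignment)
  if (gap_mode == "complete") {
    keep <- colSums(apply(m, 2L, function(col) col %in% GAP_CHARS)) == 0L
    if (!any(keep)) stop("zero comparable sites after complete deletion",
                         call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !(m[i, ] %in% GAP_CHARS) & !(m[j, ] %in% GAP_CHARS)
    if (!any(ok)) stop("zero comparable sites for pair ", rownames(m)[i],
                       "/", rownames(m)[j], call. = FALSE)
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 1) stop("saturated distance for pair ", rownames(m)[i], "/",
                     rownames(m)[j], call. = FALSE)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: Q-matrix minimization with
#' lowest-(row, column) tie-breaking, the usual branch-length formulas,
#' and distance reduction. Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sibling edge; raw (unclamped)
#' lengths are kept in the `raw_edge.length` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames", call. = FALSE)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  labels <- taxa            # newick fragment per active node
  raw <- new.env()          # raw edge lengths, keyed by newick fragment
  fmt <- function(x) sprintf("%.17g", x)
  while (length(labels) > 3L) {
    n <- nrow(d)
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest (row, column) pair among ties, scanning column-major i < j
    best <- c(0L, 0L); bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (q[i, j] < bestq - 1e-12) { bestq <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li_raw <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj_raw <- d[i, j] - li_raw
    li <- li_raw; lj <- lj_raw
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(li),
                         labels[j], fmt(lj))
    assign(new_label, c(li_raw, lj_raw), envir = raw)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    labels <- c(labels[keep], new_label)
    dimnames(d2) <- list(labels, labels)
    d <- d2
  }
  # final 3-node star: a = (d12 + d13 - d23) / 2 etc.
  l1_raw <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2_raw <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3_raw <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l <- pmax(c(l1_raw, l2_raw, l3_raw), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", labels[1], fmt(l[1]),
                 labels[2], fmt(l[2]), labels[3], fmt(l[3]))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_edge.length") <- tree$edge.length
  tree
}

# Canonical keys for the internal (non-trivial) splits of an unrooted tree:
# the tip-label set on the side not containing the alphabetically first
# taxon, sorted and collapsed.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- tree$tip.label[idx]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys[!is.na(keys)]
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected distance matrix and NJ tree per replicate, and scores
#' each internal split of the point-estimate tree as the percentage of
#' successful replicates containing it. Replicates yielding a saturated
#' distance are skipped and counted. Taxa are canonically sorted before
#' the protocol, making supports invariant to input order.
#'
#' @param alignment named character vector of aligned sequences (>= 4 taxa
#'   for non-trivial splits).
#' @param n_replicates bootstrap replicate count (default 500).
#' @param seed integer RNG seed.
#' @param gap_mode see [poisson_dist_matrix()].
#' @return list with `tree` (point tree; `node.label` holds supports in
#'   [0, 100], empty for the root and trivial nodes), `supports` (named
#'   numeric vector keyed by split), `n_skipped`, `n_used`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 500L, seed = 1L,
                              gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  alignment <- alignment[order(names(alignment))]
  tree <- nj_tree(poisson_dist_matrix(alignment, gap_mode))
  if (n_replicates == 0L)
    return(list(tree = tree, supports = setNames(numeric(0), character(0)),
                n_skipped = 0L, n_used = 0L))
  point_splits <- tree_splits(tree)
  hits <- setNames(numeric(length(point_splits)), point_splits)
  m <- aln_matrix(alignment)
  set.seed(seed)
  n_skipped <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot_aln <- setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                               collapse = ""), rownames(m))
    bd <- tryCatch(poisson_dist_matrix(boot_aln, gap_mode),
                   error = function(e) NULL)
    if (is.null(bd)) { n_skipped <- n_skipped + 1L; next }
    bs <- tree_splits(nj_tree(bd))
    found <- point_splits %in% bs
    hits[found] <- hits[found] + 1
  }
  n_used <- n_replicates - n_skipped
  supports <- if (n_used > 0) 100 * hits / n_used else hits * NA_real_
  # attach supports as internal node labels
  n_tip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  labs <- vapply(seq_along(parts), function(k) {
    side <- tree$tip.label[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }, character(1))
  tree$node.label <- labs
  list(tree = tree, supports = supports, n_skipped = n_skipped,
       n_used = n_used)
}

#' Sum of branch lengths of a tree
#'
#' @param tree an [ape::phylo] object with edge lengths.
#' @return total branch length.
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no edge lengths", call. = FALSE)
  sum(tree$edge.length)
}

#' Read an aligned protein FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}
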