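# Built-in single-end seed-and-extend mapper. Ungapped by design: the
# survey only consumes mapped/unmapped status plus position, and the
# synthetic reads carry substitutions only.

#' Build a k-mer index over a reference set
#'
#' Indexes every k-mer occurrence of every reference on both strands.
#'
#' @param references named character vector of reference sequences.
#' @param k seed length (default 15; must be in 11..31 and no longer than
#'   the shortest reference).
#' @return a `mapper_index` object.
#' @export
build_index <- function(references, k = 15L) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named", call. = FALSE)
  ptr <- cpp_build_index(unname(references), names(references), as.integer(k))
  info <- cpp_index_info(ptr)
  structure(list(ptr = ptr, k = info$k, ref_names = info$ref_names,
                 ref_lengths = setNames(nchar(references), names(references)),
                 n_entries = info$n_entries),
            class = "mapper_index")
}

#' @export
print.mapper_index <- function(x, ...) {
  cat(sprintf("mapper_index: %d reference(s), k = %d, %.0f k-mer entries\n",
              length(x$ref_names), x$k, x$n_entries))
  invisible(x)
}

#' Map reads against an index
#'
#' Every read offset is seeded; candidate ungapped placements are scored by
#' full Hamming distance on the appropriate strand. A read is reported
#' mapped only when its best placement passes the mismatch budget
#' (`floor(max_mismatch_fraction * read_length)`) and strictly beats the
#' second-best candidate; ties leave the read unmapped (conservative, to
#' avoid false anchor loci).
#'
#' @param reads character vector of read sequences (each at least k long).
#' @param index a [build_index()] result.
#' @param max_mismatch_fraction maximum mismatch fraction (default 0.06).
#' @param ids optional read identifiers.
#' @return data.frame with columns `id`, `seq`, `mapped`, `ref`, `pos`
#'   (0-based leftmost, NA when unmapped), `strand` ("+"/"-"), `nm`.
#' @export
map_reads <- function(reads, index, max_mismatch_fraction = 0.06, ids = NULL) {
  stopifnot(inherits(index, "mapper_index"))
  if (any(nchar(reads) < index$k))
    stop("read shorter than seed length k", call. = FALSE)
  res <- cpp_map_reads(index$ptr, reads, max_mismatch_fraction)
  data.frame(id = if (is.null(ids)) sprintf("read%d", seq_along(reads)) else ids,
             seq = reads, mapped = res$mapped,
             ref = ifelse(res$mapped, index$ref_names[res$ref], NA_character_),
             pos = res$pos,
             strand = ifelse(res$mapped, c("+", "-")[res$strand + 1L],
                             NA_character_),
             nm = res$nm, stringsAsFactors = FALSE)
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read one read sequence.
#' @return one-row data.frame as in [map_reads()].
#' @export
map_read <- function(read, index, max_mismatch_fraction = 0.06) {
  map_reads(read, index, max_mismatch_fraction)
}

#' Map read pairs
#'
#' Both mates are mapped independently (the mapper scores both strands, so
#' the FR orientation of simulated mate 2 is handled without explicit
#' reverse complementing). Output rows come in mate-1/mate-2 order per pair.
#'
#' @param fq1,fq2 data.frames with columns `id`, `seq` (as returned by
#'   [read_fastq()] or [simulate_paired_reads()]); identifiers must match
#'   pairwise.
#' @param index a [build_index()] result.
#' @param max_mismatch_fraction maximum mismatch fraction.
#' @return data.frame with columns `id`, `mate` (1 or 2), `seq`, `mapped`,
#'   `ref`, `pos`, `strand`, `nm`.
#' @export
map_pairs <- function(fq1, fq2, index, max_mismatch_fraction = 0.06) {
  if (nrow(fq1) != nrow(fq2))
    stop("mate files have different record counts", call. = FALSE)
  if (nrow(fq1) == 0L)
    return(data.frame(id = character(0), mate = integer(0), seq = character(0),
                      mapped = logical(0), ref = character(0), pos = integer(0),
                      strand = character(0), nm = integer(0)))
  if (!all(fq1$id == fq2$id))
    stop("mate identifiers do not match pairwise", call. = FALSE)
  a1 <- map_reads(fq1$seq, index, max_mismatch_fraction, ids = fq1$id)
  a2 <- map_reads(fq2$seq, index, max_mismatch_fraction, ids = fq2$id)
  a1$mate <- 1L
  a2$mate <- 2L
  out <- rbind(a1, a2)
  out <- out[order(match(out$id, fq1$id), out$mate), ]
  rownames(out) <- NULL
  out[, c("id", "mate", "seq", "mapped", "ref", "pos", "strand", "nm")]
}
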