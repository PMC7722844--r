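#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Reporting-grade rounding: 0.5 always rounds away from zero, unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a per-stage child seed from a root seed; keeps results < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write reads to a FASTQ file
#'
#' Quality strings are constant 'I' (Phred 40): downstream stages never
#' consume base qualities.
#'
#' @param ids read identifiers.
#' @param seqs read sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  out <- character(4L * length(ids))
  idx <- seq_along(ids)
  out[4L * idx - 3L] <- paste0("@", ids)
  out[4L * idx - 2L] <- seqs
  out[4L * idx - 1L] <- "+"
  out[4L * idx] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("[ /].*$", "", ids)
  data.frame(id = ids, seq = lines[seq(2L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}

# TSV helpers: all tabular outputs share one dialect (tab, header, no quotes).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
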