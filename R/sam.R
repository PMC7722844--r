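# SAM reading/writing for paired alignments. Only the fields the survey
# consumes are represented: identifiers, mapped/unmapped status, reference,
# 0-based position, strand, mismatch count (NM tag), and mate linkage via
# the standard flag bits (0x1 paired, 0x4 unmapped, 0x8 mate unmapped,
# 0x10 reverse, 0x20 mate reverse, 0x40 first, 0x80 second). Rsamtools
# consumes BAM, not headerless text SAM, so the (purely tabular) SAM lines
# are written and parsed directly.

flag_bits <- c(paired = 1L, unmapped = 4L, mate_unmapped = 8L,
               reverse = 16L, mate_reverse = 32L, first = 64L, second = 128L)

#' Write paired alignments to a SAM file
#'
#' Coordinates are converted from the internal 0-based convention to SAM's
#' 1-based columns; reverse-strand records store the reverse complement of
#' the read, per the standard.
#'
#' @param alignments data.frame as returned by [map_pairs()].
#' @param ref_lengths named integer vector of reference lengths (for
#'   `@SQ` header lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  a <- alignments[order(match(alignments$id, unique(alignments$id)),
                        alignments$mate), ]
  stopifnot(all(table(a$id) == 2L))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  i1 <- which(a$mate == 1L); i2 <- which(a$mate == 2L)
  fmt_mate <- function(self, mate) {
    flag <- flag_bits[["paired"]] +
      ifelse(self$mate == 1L, flag_bits[["first"]], flag_bits[["second"]]) +
      ifelse(self$mapped, 0L, flag_bits[["unmapped"]]) +
      ifelse(mate$mapped, 0L, flag_bits[["mate_unmapped"]]) +
      ifelse(self$mapped & self$strand == "-", flag_bits[["reverse"]], 0L) +
      ifelse(mate$mapped & mate$strand == "-", flag_bits[["mate_reverse"]], 0L)
    rname <- ifelse(self$mapped, self$ref, "*")
    pos <- ifelse(self$mapped, self$pos + 1L, 0L)
    cigar <- ifelse(self$mapped, paste0(nchar(self$seq), "M"), "*")
    rnext <- ifelse(mate$mapped,
                    ifelse(self$mapped & mate$ref == self$ref, "=", mate$ref),
                    "*")
    pnext <- ifelse(mate$mapped, mate$pos + 1L, 0L)
    seq <- ifelse(self$mapped & self$strand == "-", revcomp(self$seq), self$seq)
    line <- paste(self$id, flag, rname, pos, ifelse(self$mapped, 60L, 0L),
                  cigar, rnext, pnext, 0L, seq, "*", sep = "\t")
    ifelse(self$mapped, paste0(line, "\tNM:i:", self$nm), line)
  }
  body <- character(nrow(a))
  body[i1] <- fmt_mate(a[i1, ], a[i2, ])
  body[i2] <- fmt_mate(a[i2, ], a[i1, ])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read paired alignments from a SAM file
#'
#' Inverse of [write_sam()]: reproduces the internal alignment data.frame
#' (0-based positions, original read orientation).
#'
#' @param path SAM file.
#' @return data.frame with columns `id`, `mate`, `seq`, `mapped`, `ref`,
#'   `pos`, `strand`, `nm`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(id = character(0), mate = integer(0), seq = character(0),
                      mapped = logical(0), ref = character(0), pos = integer(0),
                      strand = character(0), nm = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  field <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(field(2))
  mapped <- bitwAnd(flag, flag_bits[["unmapped"]]) == 0L
  strand <- ifelse(mapped,
                   ifelse(bitwAnd(flag, flag_bits[["reverse"]]) > 0L, "-", "+"),
                   NA_character_)
  seq <- field(10)
  seq[mapped & strand == "-"] <- revcomp(seq[mapped & strand == "-"])
  nm <- vapply(parts, function(p) {
    tag <- grep("^NM:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  out <- data.frame(
    id = field(1),
    mate = ifelse(bitwAnd(flag, flag_bits[["first"]]) > 0L, 1L, 2L),
    seq = seq, mapped = mapped,
    ref = ifelse(mapped, field(3), NA_character_),
    pos = ifelse(mapped, as.integer(field(4)) - 1L, NA_integer_),
    strand = strand, nm = nm, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
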