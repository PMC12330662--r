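#' Reverse-complement nucleotide strings
#'
#' Vectorised, IUPAC-aware reverse complement on plain character vectors,
#' used throughout read simulation and demultiplexing. (A compiled kernel is
#' used because the demultiplexer calls it per read.)
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  .revcomp_cpp(x)
}

## Parse a CIGAR string into an ops/lengths data.frame.
.cigar_runs <- function(cigar) {
  data.frame(
    op = GenomicAlignments::explodeCigarOps(cigar)[[1]],
    length = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]],
    stringsAsFactors = FALSE
  )
}

## Collapse an ops/lengths pair back into a CIGAR string.
.runs_to_cigar <- function(ops, lengths) {
  paste0(lengths, ops, collapse = "")
}

#' Fraction of read bases consumed by the alignment
#'
#' For each CIGAR string, the proportion of read bases carried by aligned
#' operations (`M`, `=`, `X`, `I`) out of all read bases (aligned plus
#' soft-clipped). Reads aligned end-to-end score 1; heavily clipped, spurious
#' alignments score low and are removed by [filter_alignments()].
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Numeric vector in `[0, 1]`.
#' @export
aligned_fraction <- function(cigar) {
  tab <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- tab[, "M"] + tab[, "="] + tab[, "X"] + tab[, "I"]
  total <- aligned + tab[, "S"]
  out <- aligned / total
  out[total == 0] <- 0
  unname(out)
}

## Write a data.frame as a plain TSV (no quoting, no row names).
.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

## 0-based half-open interval overlap width.
.overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
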