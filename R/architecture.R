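## Pre-computed set of 16-nt sample barcodes with pairwise Levenshtein
## distance >= 7, i.e. more than twice the demultiplexing mismatch tolerance
## of 3, so no read can ever sit within tolerance of two barcodes at once.
.BARCODES <- c(
  "AAAACTCCATGTGTAA", "CTCCGGAAGTAGAATC", "TTGCACTCGGCCTTTC",
  "CATATCTCGTGAACCC", "CCTGCACGCCCTAAAG", "TACAATTAGGATATTC",
  "ATCCCTACACTGTATA", "TGCCGAACGTTCTAAT", "AAACGACTTAGCAACA",
  "AGTCGCCTAGAAAGGT", "ACCGCTGGCATATCAC", "GCCTCCCGCTTGCCGT",
  "CTTCAACTTCATGACC", "CCTCAAGCCGGAGTCT", "AGGCTTTGAAACAGCT",
  "TACGTGAGTCGTCGGA", "GGACACACTAGTCGCC", "CTTGAGAGCACTCCAG",
  "TCCAGGCGAGGTATCC", "ACGACGATACGACTCG", "GCTAGCAAACGCGCGG",
  "TTTATCTATGCAGCTA", "ATATCCTTAGTAGTCG", "GTCATCAGGCGGCATC"
)

## Template-switching common primer appended (reverse-complemented) at the
## far end of every first-strand cDNA; the standard ISPCR/SMART sequence.
.DEFAULT_CP <- "AAGCAGTGGTATCAACGCAGAGT"

#' Default sample barcode set
#'
#' Returns up to 24 length-16 barcodes whose pairwise edit distance is at
#' least 7. Because the demultiplexer tolerates at most 3 edits, a read can
#' match at most one of these barcodes, which makes cross-sample
#' misassignment impossible by the triangle inequality.
#'
#' @param n Number of barcodes to return (1--24).
#' @return Named character vector (`BC01`, `BC02`, ...).
#' @export
#' @examples
#' default_barcodes(6)
default_barcodes <- function(n = 24L) {
  n <- as.integer(n)
  if (n < 1L || n > length(.BARCODES))
    stop("n must be between 1 and ", length(.BARCODES))
  bc <- .BARCODES[seq_len(n)]
  names(bc) <- sprintf("BC%02d", seq_len(n))
  bc
}

#' Describe the architecture of barcoded oligo-dT reads
#'
#' Captures everything about how a raw read is laid out and corrupted: the
#' sample barcodes, the common primer (CP), the poly-T tract length range,
#' per-base substitution/indel error rates, the 5'-truncation distribution
#' (oligo-dT priming anchors the 3' end of the transcript, so reads lose
#' sequence from the transcript 5' end), and the probability that a read is
#' recorded in the forward layout
#' `[barcode][poly-T][revcomp(cDNA)][revcomp(CP)]` rather than its reverse
#' complement.
#'
#' @param barcodes Named character vector of barcode sequences, each at least
#'   12 nt, pairwise edit distance at least 7.
#' @param cp Common-primer sequence (at least 10 nt).
#' @param polyt_len Integer range `c(min, max)` of simulated poly-T tract
#'   lengths.
#' @param error_rate Per-base substitution probability.
#' @param indel_rate Per-base insertion/deletion probability (default 0 so
#'   mismatch counts in unit tests are exactly predictable; the demultiplexer
#'   itself always uses full edit distance).
#' @param truncation Either `NULL` (full-length reads) or a numeric
#'   `c(shape1, shape2)` giving the Beta distribution of the fraction of the
#'   transcript retained from its 3' end.
#' @param forward_prob Probability that a read is emitted in the forward
#'   layout.
#' @return An object of class `read_architecture`.
#' @export
#' @examples
#' arch <- read_architecture(barcodes = default_barcodes(6))
read_architecture <- function(barcodes = default_barcodes(6L),
                              cp = .DEFAULT_CP,
                              polyt_len = c(12L, 20L),
                              error_rate = 0.02,
                              indel_rate = 0,
                              truncation = c(shape1 = 8, shape2 = 2),
                              forward_prob = 0.5) {
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("barcodes must be uniquely named")
  if (any(nchar(barcodes) < 12L))
    stop("all barcodes must be at least 12 nt long")
  if (length(barcodes) > 1L) {
    d <- utils::adist(barcodes)
    diag(d) <- NA
    if (min(d, na.rm = TRUE) < 7L)
      stop("barcodes must have pairwise edit distance >= 7 ",
           "(more than twice the mismatch tolerance of 3)")
  }
  if (nchar(cp) < 10L) stop("common primer must be at least 10 nt long")
  stopifnot(length(polyt_len) == 2L, polyt_len[1] <= polyt_len[2],
            polyt_len[1] >= 1)
  stopifnot(error_rate >= 0, error_rate < 1, indel_rate >= 0, indel_rate < 1)
  if (!is.null(truncation))
    stopifnot(length(truncation) == 2L, all(truncation > 0))
  stopifnot(forward_prob >= 0, forward_prob <= 1)
  structure(list(
    barcodes = barcodes, cp = cp,
    polyt_len = as.integer(polyt_len),
    error_rate = error_rate, indel_rate = indel_rate,
    truncation = truncation, forward_prob = forward_prob
  ), class = "read_architecture")
}

#' Describe the experimental design of a simulated study
#'
#' Conditions are defined by isoform mixing proportions: for each condition a
#' named vector `c(spliced = ..., retained = ...)` giving the probability
#' that a transcript of a regulated gene carries the retained intron. All
#' other genes share a flat `background_retention` in every condition, so by
#' default exactly the regulated gene changes between conditions while the
#' rest provide null regions.
#'
#' @param conditions Named list of per-condition mixing proportions, each a
#'   numeric vector with entries `spliced` and `retained` summing to 1.
#' @param n_replicates Biological replicates per condition (default 3).
#' @param reads_per_gene Reads simulated per gene per replicate.
#' @param regulated_genes Indices of genes that follow the per-condition
#'   proportions; the remainder use `background_retention`.
#' @param background_retention Retained-isoform proportion for non-regulated
#'   genes, identical across conditions.
#' @param exact_mix If `TRUE`, the retained-read count per (gene, replicate)
#'   is `round(p * n)` instead of a binomial draw; used for noise-free
#'   boundary-recovery checks.
#' @return An object of class `condition_design`.
#' @export
#' @examples
#' condition_design(n_replicates = 3, reads_per_gene = 100)
condition_design <- function(conditions = list(
                               ctrl = c(spliced = 0.05, retained = 0.95),
                               stress = c(spliced = 0.65, retained = 0.35)),
                             n_replicates = 3L,
                             reads_per_gene = 200L,
                             regulated_genes = 1L,
                             background_retention = 0.30,
                             exact_mix = FALSE) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stop("conditions must be a uniquely named list")
  for (cn in names(conditions)) {
    p <- conditions[[cn]]
    if (!all(c("spliced", "retained") %in% names(p)))
      stop("condition '", cn, "' must name 'spliced' and 'retained' proportions")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("mixing proportions for condition '", cn,
           "' must be non-negative and sum to 1")
  }
  stopifnot(n_replicates >= 1L, reads_per_gene >= 1L,
            background_retention >= 0, background_retention <= 1)
  structure(list(
    conditions = conditions,
    n_replicates = as.integer(n_replicates),
    reads_per_gene = as.integer(reads_per_gene),
    regulated_genes = as.integer(regulated_genes),
    background_retention = background_retention,
    exact_mix = isTRUE(exact_mix)
  ), class = "condition_design")
}
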