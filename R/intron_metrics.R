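#' Splicing fraction from intron-spanning reads
#'
#' The canonical targeted splicing readout (as used for the XBP1
#' unconventional intron): among reads whose alignment footprint spans the
#' intron plus a small flank, the fraction whose alignment lacks the intron
#' — i.e. carries an `N` (spliced-out) run covering at least `lack_frac` of
#' the interval, tolerant of splice-site wobble in long reads. Uncertainty
#' is reported on the logit scale with the binomial delta-method standard
#' error `sqrt(1/k + 1/(n - k))`, back-transformed to a two-standard-error
#' interval in fraction space.
#'
#' @param alignments Data.frame with `chrom`, `pos` (0-based) and `cigar`.
#' @param intron Numeric `c(start, end)`, 0-based half-open genomic
#'   interval.
#' @param chrom Optional chromosome; alignments on other chromosomes are
#'   ignored.
#' @param flank Bases beyond each end of the intron a read must cover to
#'   count as spanning (default 10).
#' @param lack_frac Fraction of the intron an `N` run must cover for the
#'   read to count as spliced (default 0.9).
#' @return A list of class `splicing_fraction`: `spliced_count` (k),
#'   `spanning_count` (n), `fraction` (k/n), `logit_se`, `interval`
#'   (fraction +/- 2 SE, back-transformed), `corrected` (TRUE when k was 0
#'   or n and a +0.5 continuity correction was applied to the SE and
#'   interval). With no spanning reads, `fraction` is `NA`.
#' @export
intron_spanning_fraction <- function(alignments, intron, chrom = NULL,
                                     flank = 10L, lack_frac = 0.9) {
  stopifnot(length(intron) == 2L, intron[2] > intron[1])
  if (!is.null(chrom))
    alignments <- alignments[alignments$chrom == chrom, , drop = FALSE]
  ilen <- intron[2] - intron[1]
  fw <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
  fs <- alignments$pos
  fe <- fs + fw
  spanning <- fs <= intron[1] - flank & fe >= intron[2] + flank
  idx <- which(spanning)
  lacking <- logical(length(idx))
  if (length(idx)) {
    nr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      alignments$cigar[idx], pos = alignments$pos[idx] + 1L, ops = "N")
    lacking <- vapply(seq_along(idx), function(j) {
      r <- nr[[j]]
      if (length(r) == 0) return(FALSE)
      ov <- .overlap_width(IRanges::start(r) - 1L, IRanges::end(r),
                           intron[1], intron[2])
      any(ov >= lack_frac * ilen)
    }, logical(1))
  }
  n <- length(idx)
  k <- sum(lacking)
  if (n == 0)
    return(structure(list(spliced_count = 0L, spanning_count = 0L,
                          fraction = NA_real_, logit_se = NA_real_,
                          interval = c(NA_real_, NA_real_),
                          corrected = FALSE),
                     class = "splicing_fraction"))
  fraction <- k / n
  corrected <- k == 0L || k == n
  kk <- if (corrected) k + 0.5 else k
  nn <- if (corrected) n + 1 else n
  logit_se <- sqrt(1 / kk + 1 / (nn - kk))
  centre <- qlogis(kk / nn)
  interval <- plogis(centre + c(-2, 2) * logit_se)
  structure(list(spliced_count = as.integer(k), spanning_count = n,
                 fraction = fraction, logit_se = logit_se,
                 interval = interval, corrected = corrected),
            class = "splicing_fraction")
}

#' @export
print.splicing_fraction <- function(x, ...) {
  cat(sprintf(
    "<splicing_fraction> %d/%d spliced = %.3f (logit SE %.3f, 2SE interval %.3f-%.3f)\n",
    x$spliced_count, x$spanning_count, x$fraction, x$logit_se,
    x$interval[1], x$interval[2]))
  invisible(x)
}

#' Splicing fraction from gel band intensities
#'
#' Computes splicing from the background-corrected band intensities of the
#' unspliced product, the spliced product and their hybrid heteroduplex
#' (which carries one strand of each, hence the half weight):
#' `(s + h/2) / (u + s + h)`. The result is invariant to rescaling all
#' three intensities.
#'
#' @param u Unspliced band intensity.
#' @param s Spliced band intensity.
#' @param h Hybrid band intensity (default 0).
#' @return Splicing fraction in `[0, 1]`; vectorised over inputs.
#' @export
#' @examples
#' gel_splicing_fraction(u = 50, s = 30, h = 20)  # 0.40
gel_splicing_fraction <- function(u, s, h = 0) {
  if (any(u < 0 | s < 0 | h < 0))
    stop("band intensities must be non-negative")
  tot <- u + s + h
  if (any(tot == 0))
    stop("band intensities must not all be zero")
  (s + h / 2) / tot
}
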