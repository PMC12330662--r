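#' Clean a CIGAR into present/absent reference runs
#'
#' Prepares a spliced alignment's CIGAR for %SI pileup: insertions and soft
#' clips are dropped (they consume no reference), `M`/`=`/`X` runs become
#' `present` and `N`/`D` runs `absent`, then any run shorter than `min_run`
#' bases is merged into the preceding run (adopting its class) and adjacent
#' same-class runs are coalesced. The merge rule absorbs alignment noise:
#' in particular, small deletions are folded into their flanking matches
#' rather than masquerading as splicing. A short leading run, which has no
#' preceding run, merges forward into the following run; when that happens
#' the result carries attribute `leading_merge = TRUE`.
#'
#' @param cigar A CIGAR string.
#' @param min_run Minimum run length (default 10); shorter runs are merged.
#' @return Data.frame with columns `class` (`"present"`/`"absent"`) and
#'   `length`, in reference order.
#' @export
#' @examples
#' preprocess_cigar("100M5D100M")  # one present run of 205
#' preprocess_cigar("100M50N100M") # present/absent/present
preprocess_cigar <- function(cigar, min_run = 10L) {
  runs <- .cigar_runs(cigar)
  runs <- runs[!runs$op %in% c("I", "S", "H", "P"), , drop = FALSE]
  cls <- ifelse(runs$op %in% c("M", "=", "X"), "present", "absent")
  len <- runs$length
  leading <- FALSE
  coalesce <- function(cls, len) {
    if (length(cls) < 2L) return(list(cls = cls, len = len))
    keep <- c(TRUE, cls[-1] != cls[-length(cls)])
    grp <- cumsum(keep)
    list(cls = cls[keep],
         len = as.integer(tapply(len, grp, sum)))
  }
  z <- coalesce(cls, len)
  cls <- z$cls; len <- z$len
  repeat {
    short <- which(len < min_run)
    if (length(short) == 0 || length(len) == 1L) break
    i <- short[1]
    if (i == 1L) {           # no preceding run: merge forward
      leading <- TRUE
      len[2] <- len[2] + len[1]
      cls <- cls[-1]; len <- len[-1]
    } else {
      len[i - 1] <- len[i - 1] + len[i]
      cls <- cls[-i]; len <- len[-i]
    }
    z <- coalesce(cls, len)
    cls <- z$cls; len <- z$len
  }
  structure(data.frame(class = cls, length = as.integer(len),
                       stringsAsFactors = FALSE, row.names = NULL),
            leading_merge = leading)
}

#' Flag short, spurious alignments
#'
#' Keeps reads whose aligned fraction (proportion of read bases in
#' `M`/`=`/`X`/`I` operations, see [aligned_fraction()]) strictly exceeds
#' `min_frac`; a read aligned at exactly the threshold is dropped.
#'
#' @param alignments Data.frame with an `aligned_fraction` column (computed
#'   from the `cigar` column if absent).
#' @param min_frac Aligned-fraction threshold (default 0.8).
#' @return Data.frame with logical `keep` and character `reason` (`NA` for
#'   kept reads, `"low_aligned_fraction"` otherwise).
#' @export
filter_alignments <- function(alignments, min_frac = 0.8) {
  frac <- if ("aligned_fraction" %in% names(alignments))
    alignments$aligned_fraction else aligned_fraction(alignments$cigar)
  keep <- frac > min_frac
  data.frame(keep = keep,
             reason = ifelse(keep, NA_character_, "low_aligned_fraction"),
             stringsAsFactors = FALSE)
}

#' Accumulate a per-base %SI pileup for one gene
#'
#' Converts the cleaned runs of each read into two per-position counters
#' over the gene span: `spliced_in`, the number of reads whose alignment
#' includes a base at the position (mismatches count), and `spanning`, the
#' number of reads whose alignment crosses the position. The first and last
#' cleaned runs of every read contribute to neither counter, which
#' suppresses the alignment variability of read ends; a read reduced to two
#' or fewer runs therefore contributes nothing. Interior `present` runs
#' increment both counters, interior `absent` runs (spliced-out sequence)
#' increment `spanning` only, so `spliced_in / spanning` is the per-base
#' percent-spliced-in.
#'
#' @param alignments Data.frame of alignments for this gene (`pos` 0-based,
#'   `cigar`), already filtered with [filter_alignments()].
#' @param gene A [gene_model()]; the pileup covers its span.
#' @param min_run Run-merge threshold passed to [preprocess_cigar()].
#' @return An object of class `splice_pileup`: list with `gene_id`, `chrom`,
#'   `start` (0-based span start) and integer vectors `spliced_in`,
#'   `spanning` over the span.
#' @export
accumulate_pileup <- function(alignments, gene, min_run = 10L) {
  gs <- gene$start; ge <- gene$end
  w <- ge - gs
  spliced <- integer(w)
  spanning <- integer(w)
  for (i in seq_len(nrow(alignments))) {
    runs <- preprocess_cigar(alignments$cigar[i], min_run = min_run)
    nr <- nrow(runs)
    if (nr <= 2L) next
    ends <- alignments$pos[i] + cumsum(runs$length)
    starts <- ends - runs$length
    for (j in 2:(nr - 1L)) {
      s <- max(starts[j], gs); e <- min(ends[j], ge)
      if (e <= s) next
      idx <- (s - gs + 1L):(e - gs)
      spanning[idx] <- spanning[idx] + 1L
      if (runs$class[j] == "present")
        spliced[idx] <- spliced[idx] + 1L
    }
  }
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom, start = gs,
                 spliced_in = spliced, spanning = spanning),
            class = "splice_pileup")
}

#' @export
print.splice_pileup <- function(x, ...) {
  cat(sprintf("<splice_pileup> %s %s:%d-%d, max spanning %d\n",
              x$gene_id, x$chrom, x$start,
              x$start + length(x$spanning), max(x$spanning)))
  invisible(x)
}

#' Per-position percent-spliced-in of a pileup
#'
#' @param pileup A `splice_pileup`.
#' @return Numeric vector `spliced_in / spanning` (`NaN` where no read
#'   spans).
#' @export
psi <- function(pileup) {
  pileup$spliced_in / pileup$spanning
}

#' Per-gene pileups for a set of samples
#'
#' Driver combining gene assignment, the aligned-fraction filter and
#' [accumulate_pileup()]: returns one pileup per (sample, gene).
#'
#' @param alignments Data.frame of alignments with `read_id`, `chrom`,
#'   `pos`, `cigar` and a `sample_id` column.
#' @param genes Named list of [gene_model()] objects.
#' @param gene_ids Optional precomputed [assign_genes()] vector.
#' @param min_run Run-merge threshold.
#' @param min_frac Aligned-fraction threshold.
#' @return Nested list: `pileups[[sample_id]][[gene_id]]` is a
#'   `splice_pileup`.
#' @export
gene_pileups <- function(alignments, genes, gene_ids = NULL,
                         min_run = 10L, min_frac = 0.8) {
  keep <- filter_alignments(alignments, min_frac = min_frac)$keep
  alignments <- alignments[keep, , drop = FALSE]
  if (is.null(gene_ids)) gene_ids <- assign_genes(alignments, genes)
  else gene_ids <- gene_ids[keep]
  samples <- sort(unique(alignments$sample_id))
  out <- lapply(samples, function(s) {
    sel <- alignments$sample_id == s & !is.na(gene_ids)
    sub <- alignments[sel, , drop = FALSE]
    gid <- gene_ids[sel]
    pl <- lapply(names(genes), function(g)
      accumulate_pileup(sub[gid == g, , drop = FALSE], genes[[g]],
                        min_run = min_run))
    names(pl) <- names(genes)
    pl
  })
  names(out) <- samples
  out
}

#' Write a %SI track as BEDGraph
#'
#' @param pileup A `splice_pileup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi_bedgraph <- function(pileup, path) {
  v <- psi(pileup)
  ok <- which(is.finite(v))
  lines <- sprintf("%s\t%d\t%d\t%.6g", pileup$chrom,
                   pileup$start + ok - 1L, pileup$start + ok, v[ok])
  writeLines(c(sprintf("track type=bedGraph name=%s_psi", pileup$gene_id),
               lines), path)
  invisible(path)
}
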