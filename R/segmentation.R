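#' Coverage mask across samples
#'
#' A genomic position is kept only when every sample spans it at least
#' `min_cov` times and, within every condition, the mean spanning coverage
#' across that condition's replicates is at least `mean_cov`.
#'
#' @param spanning Integer matrix of spanning counts, positions x samples.
#' @param conditions Character vector, one condition label per column.
#' @param min_cov Per-sample minimum coverage (default 5).
#' @param mean_cov Per-condition minimum mean coverage (default 20).
#' @return Logical vector over positions.
#' @export
#' @examples
#' coverage_mask(rbind(c(4, 100, 100), c(25, 25, 25)), rep("a", 3))
coverage_mask <- function(spanning, conditions, min_cov = 5, mean_cov = 20) {
  stopifnot(ncol(spanning) == length(conditions))
  keep <- apply(spanning, 1, min) >= min_cov
  for (cn in unique(conditions)) {
    sub <- spanning[, conditions == cn, drop = FALSE]
    keep <- keep & rowMeans(sub) >= mean_cov
  }
  unname(keep)
}

#' Segment a %SI signal by cumulative-average scan
#'
#' Scans the per-position spliced-in fraction left to right, maintaining the
#' cumulative mean since the current region's start; whenever a position's
#' fraction differs from that cumulative mean by more than `max_dev`, the
#' region is closed before the position and the cumulative mean restarts
#' there. Masked (low-coverage) positions are skipped without closing the
#' region and deviations of at most `max_dev` never split, so a step in %SI
#' larger than `max_dev` produces a boundary exactly at the step.
#'
#' @param psi Numeric vector of per-position spliced-in fractions.
#' @param mask Logical vector of positions to scan (default all).
#' @param max_dev Deviation threshold (default 0.1).
#' @param offset 0-based genomic coordinate of `psi[1]`, so the returned
#'   intervals are genomic.
#' @return Data.frame of maximal intervals with 0-based half-open `start`,
#'   `end`; empty when the mask removes every position.
#' @export
#' @examples
#' segment_psi(c(rep(1, 200), rep(0, 100)))  # two regions, boundary at 200
segment_psi <- function(psi, mask = rep(TRUE, length(psi)), max_dev = 0.1,
                        offset = 0L) {
  kept <- which(mask & is.finite(psi))
  if (length(kept) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0); ends <- integer(0)
  rs <- kept[1]; csum <- psi[rs]; cn <- 1L; last <- rs
  for (i in kept[-1]) {
    if (abs(psi[i] - csum / cn) > max_dev) {
      starts <- c(starts, rs); ends <- c(ends, last + 1L)
      rs <- i; csum <- psi[i]; cn <- 1L
    } else {
      csum <- csum + psi[i]; cn <- cn + 1L
    }
    last <- i
  }
  starts <- c(starts, rs); ends <- c(ends, last + 1L)
  data.frame(start = offset + starts - 1L, end = offset + ends - 1L)
}

#' Drop regions retained in no condition
#'
#' @param regions Data.frame of regions (as from [segment_psi()]).
#' @param psi_by_condition Numeric matrix, regions x conditions, of mean
#'   spliced-in fractions.
#' @param min_psi Retention floor (default 0.05): a region is kept iff its
#'   fraction reaches `min_psi` in at least one condition.
#' @return The retained subset of `regions`.
#' @export
filter_regions <- function(regions, psi_by_condition, min_psi = 0.05) {
  stopifnot(nrow(regions) == nrow(psi_by_condition))
  keep <- apply(psi_by_condition, 1, max) >= min_psi
  regions[keep, , drop = FALSE]
}

#' Summarise a region into per-sample integer counts
#'
#' For each sample, the spliced-in and spanning counters are averaged over
#' the region's masked positions and rounded to integers (round-half-to-even,
#' the R default, for bit-reproducibility). These `(k, n)` pairs feed the
#' negative-binomial retention model.
#'
#' @param region One-row data.frame (or list) with 0-based `start`, `end`.
#' @param pileups Named list of `splice_pileup` objects for one gene, one
#'   per sample.
#' @param mask Logical mask over the gene span (default keep all).
#' @return Data.frame with one row per sample: `sample_id`, `k`, `n`.
#' @export
summarize_region <- function(region, pileups,
                             mask = rep(TRUE,
                                        length(pileups[[1]]$spanning))) {
  gs <- pileups[[1]]$start
  idx <- (region$start - gs + 1L):(region$end - gs)
  idx <- idx[mask[idx]]
  if (length(idx) == 0)
    stop("region is empty after masking")
  do.call(rbind, lapply(names(pileups), function(s) {
    p <- pileups[[s]]
    data.frame(sample_id = s,
               k = as.integer(round(mean(p$spliced_in[idx]))),
               n = as.integer(round(mean(p$spanning[idx]))),
               stringsAsFactors = FALSE)
  }))
}

#' Segment one gene across samples
#'
#' Combines the per-sample pileups of a gene and partitions its span into
#' regions of homogeneous %SI: replicate pileups are pooled by summing
#' counts (weighting positions by evidence rather than averaging fractions),
#' low-coverage positions are masked with [coverage_mask()], the pooled
#' fraction is segmented with [segment_psi()], regions retained in no
#' condition are dropped with [filter_regions()], and each surviving region
#' is summarised per sample with [summarize_region()].
#'
#' @param pileups Named list (by `sample_id`) of `splice_pileup` objects for
#'   one gene.
#' @param sample_sheet Data.frame with `sample_id`, `condition`,
#'   `replicate`.
#' @param min_cov,mean_cov Coverage filters, see [coverage_mask()].
#' @param max_dev Segmentation threshold, see [segment_psi()].
#' @param min_psi Retention floor, see [filter_regions()].
#' @return A list with `regions` (data.frame: `gene_id`, `region_id`,
#'   `start`, `end`, and one `psi_<condition>` column per condition) and
#'   `counts` (long data.frame: one row per region x sample with `k`, `n`).
#'   Both empty when no position passes the coverage mask.
#' @export
segment_gene <- function(pileups, sample_sheet, min_cov = 5, mean_cov = 20,
                         max_dev = 0.1, min_psi = 0.05) {
  sample_sheet <- sample_sheet[match(names(pileups),
                                     sample_sheet$sample_id), ]
  spl <- vapply(pileups, `[[`, integer(length(pileups[[1]]$spliced_in)),
                "spliced_in")
  spa <- vapply(pileups, `[[`, integer(length(pileups[[1]]$spanning)),
                "spanning")
  gene_id <- pileups[[1]]$gene_id
  gs <- pileups[[1]]$start
  conds <- sample_sheet$condition
  mask <- coverage_mask(spa, conds, min_cov = min_cov, mean_cov = mean_cov)
  empty <- list(
    regions = data.frame(gene_id = character(0), region_id = character(0),
                         start = integer(0), end = integer(0)),
    counts = data.frame(gene_id = character(0), region_id = character(0),
                        start = integer(0), end = integer(0),
                        sample_id = character(0), condition = character(0),
                        replicate = integer(0), k = integer(0),
                        n = integer(0)))
  if (!any(mask)) return(empty)
  pooled <- rowSums(spl) / rowSums(spa)
  regions <- segment_psi(pooled, mask = mask, max_dev = max_dev,
                         offset = gs)
  ## pooled per-condition %SI over masked positions of each region
  ucond <- unique(conds)
  psi_cond <- matrix(NA_real_, nrow(regions), length(ucond),
                     dimnames = list(NULL, ucond))
  for (r in seq_len(nrow(regions))) {
    idx <- (regions$start[r] - gs + 1L):(regions$end[r] - gs)
    idx <- idx[mask[idx]]
    for (cn in ucond) {
      sel <- conds == cn
      psi_cond[r, cn] <- sum(spl[idx, sel]) / sum(spa[idx, sel])
    }
  }
  keep <- apply(psi_cond, 1, max) >= min_psi
  regions <- regions[keep, , drop = FALSE]
  psi_cond <- psi_cond[keep, , drop = FALSE]
  if (nrow(regions) == 0) return(empty)
  regions <- data.frame(
    gene_id = gene_id,
    region_id = sprintf("%s:%d-%d", gene_id, regions$start, regions$end),
    regions, stringsAsFactors = FALSE, row.names = NULL)
  colnames(psi_cond) <- paste0("psi_", ucond)
  regions <- cbind(regions, psi_cond)
  counts <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
    s <- summarize_region(regions[r, ], pileups, mask = mask)
    cbind(regions[rep(r, nrow(s)), c("gene_id", "region_id", "start",
                                     "end")],
          sample_id = s$sample_id,
          condition = sample_sheet$condition[match(s$sample_id,
                                                   sample_sheet$sample_id)],
          replicate = sample_sheet$replicate[match(s$sample_id,
                                                   sample_sheet$sample_id)],
          k = s$k, n = s$n, row.names = NULL)
  }))
  list(regions = regions, counts = counts)
}

#' Segment every gene of a study
#'
#' @param pileups Nested list as from [gene_pileups()]:
#'   `pileups[[sample_id]][[gene_id]]`.
#' @inheritParams segment_gene
#' @return As [segment_gene()], concatenated over genes.
#' @export
segment_genes <- function(pileups, sample_sheet, min_cov = 5,
                          mean_cov = 20, max_dev = 0.1, min_psi = 0.05) {
  gene_ids <- names(pileups[[1]])
  res <- lapply(gene_ids, function(g) {
    pl <- lapply(pileups, `[[`, g)
    segment_gene(pl, sample_sheet, min_cov = min_cov, mean_cov = mean_cov,
                 max_dev = max_dev, min_psi = min_psi)
  })
  list(regions = do.call(rbind, lapply(res, `[[`, "regions")),
       counts = do.call(rbind, lapply(res, `[[`, "counts")))
}

#' Write regions as BED
#'
#' @param regions Region data.frame from [segment_genes()] with a pooled
#'   %SI column per condition.
#' @param chrom Chromosome name (single value or per-region vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, chrom, path) {
  psicols <- grep("^psi_", names(regions), value = TRUE)
  score <- if (length(psicols)) round(1000 * do.call(
    pmax, c(regions[psicols], na.rm = TRUE))) else 0L
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", chrom, regions$start,
                     regions$end, regions$region_id, as.integer(score)),
             path)
  invisible(path)
}
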