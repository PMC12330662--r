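#' Assign alignments to genes by overlap ratio
#'
#' Each alignment's reference footprint (the genomic span covered by its
#' `M`/`=`/`X`/`D`/`N` operations, i.e. including skipped introns) is scored
#' against every overlapping annotation as
#' `overlap / max(annotation length, footprint length)`, and the
#' highest-scoring annotation wins. Exact score ties are broken by larger
#' overlap, then lexicographic `gene_id`. Strand is ignored: cDNA reads can
#' align to either strand. Alignments overlapping no annotation (or on a
#' chromosome absent from the annotation, which triggers a warning) are
#' unassigned (`NA`).
#'
#' @param alignments Data.frame with `chrom`, `pos` (0-based) and `cigar`
#'   columns (as from [read_alignments()] or [emit_alignments()]).
#' @param genes Named list of [gene_model()] objects.
#' @return Character vector of gene ids (`NA` where unassigned), with the
#'   winning score in attribute `"score"`.
#' @export
assign_genes <- function(alignments, genes) {
  n <- nrow(alignments)
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  gchrom <- vapply(genes, `[[`, "", "chrom")
  gstart <- vapply(genes, `[[`, 0L, "start")
  gend <- vapply(genes, `[[`, 0L, "end")
  if (any(!alignments$chrom %in% gchrom))
    warning("alignments on chromosomes absent from the annotation ",
            "are unassigned")
  fw <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
  fs <- alignments$pos
  fe <- fs + fw
  q <- GenomicRanges::GRanges(alignments$chrom,
                              IRanges::IRanges(fs + 1L, fe))
  subj <- GenomicRanges::GRanges(gchrom, IRanges::IRanges(gstart + 1L, gend))
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- .overlap_width(fs[qi], fe[qi], gstart[si], gend[si])
  score <- ov / pmax(gend[si] - gstart[si], fw[qi])
  ## best hit per query: score desc, overlap desc, gene_id asc
  o <- order(qi, -score, -ov, gene_ids[si])
  first <- !duplicated(qi[o])
  out <- rep(NA_character_, n)
  sc <- rep(NA_real_, n)
  out[qi[o][first]] <- gene_ids[si[o][first]]
  sc[qi[o][first]] <- score[o][first]
  attr(out, "score") <- sc
  out
}

#' @rdname assign_genes
#' @param alignment A single alignment: a list or one-row data.frame with
#'   `chrom`, `pos` and `cigar`.
#' @return For `assign_gene()`, a single gene id or `NA`.
#' @export
assign_gene <- function(alignment, genes) {
  df <- as.data.frame(alignment[c("chrom", "pos", "cigar")],
                      stringsAsFactors = FALSE)
  res <- assign_genes(df, genes)
  structure(res[1], score = attr(res, "score")[1])
}

#' Build the per-sample gene count table
#'
#' @param assignments Data.frame with `sample_id` and `gene_id` columns
#'   (`gene_id` `NA` for unassigned reads), one row per read.
#' @param genes Named list of [gene_model()] objects fixing the row order.
#' @return A list of class `gene_count_table` with `counts` (integer matrix,
#'   genes x samples) and `unassigned` (named integer vector per sample).
#' @export
build_counts <- function(assignments, genes) {
  gene_ids <- names(genes)
  samples <- sort(unique(assignments$sample_id))
  counts <- matrix(0L, length(gene_ids), length(samples),
                   dimnames = list(gene_ids, samples))
  assigned <- !is.na(assignments$gene_id)
  if (any(assigned)) {
    tab <- table(factor(assignments$gene_id[assigned], levels = gene_ids),
                 factor(assignments$sample_id[assigned], levels = samples))
    counts[] <- as.integer(tab)
  }
  unassigned <- vapply(samples, function(s)
    sum(!assigned & assignments$sample_id == s), 0L)
  structure(list(counts = counts, unassigned = unassigned),
            class = "gene_count_table")
}

#' @export
print.gene_count_table <- function(x, ...) {
  cat(sprintf("<gene_count_table> %d genes x %d samples, %d assigned, %d unassigned\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              sum(x$unassigned)))
  invisible(x)
}

#' Filter differential-expression results by significance thresholds
#'
#' Keeps genes with Benjamini-Hochberg adjusted p-value at most `fdr` and
#' absolute log2 fold-change at least `lfc`. The differential-expression fit
#' itself is delegated to an external engine (e.g. DESeq2 on the
#' [build_counts()] table); only the thresholds are applied here.
#'
#' @param results Data.frame with columns `gene_id`, `log2fc` and `padj`.
#' @param fdr Adjusted p-value ceiling (default 0.05).
#' @param lfc Absolute log2 fold-change floor (default 0.5).
#' @return Character vector of significant gene ids.
#' @export
#' @examples
#' de <- data.frame(gene_id = c("a", "b"), log2fc = c(0.6, 0.4),
#'                  padj = c(0.04, 0.04))
#' de_threshold_filter(de)
de_threshold_filter <- function(results, fdr = 0.05, lfc = 0.5) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  keep <- !is.na(results$padj) & !is.na(results$log2fc) &
    results$padj <= fdr & abs(results$log2fc) >= lfc
  results$gene_id[keep]
}

#' Write a gene count table as TSV (genes x samples)
#'
#' @param tbl A `gene_count_table` from [build_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(tbl, path) {
  df <- data.frame(gene_id = rownames(tbl$counts), tbl$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}
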