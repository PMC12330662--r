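#' Construct a gene model
#'
#' A gene model is a genomic span on a chromosome with an ordered,
#' non-overlapping exon structure. All coordinates are 0-based, half-open;
#' conversion to 1-based happens only at SAM/GTF boundaries. Introns are the
#' exact complement of the exons within the span and must each be at least
#' 20 bases so that segmentation boundaries remain detectable under the
#' 10-base run-merge rule.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 0-based half-open `(start, end)` exon
#'   intervals, sorted and non-overlapping.
#' @return An object of class `gene_model`.
#' @export
#' @examples
#' g <- gene_model("g1", "chr1", "+", cbind(c(0, 150), c(100, 250)))
#' gene_introns(g)
gene_model <- function(gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene must have at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("exons must have positive width")
  if (is.unsorted(exons[, 1], strictly = TRUE) ||
      any(utils::head(exons[, 2], -1) > utils::tail(exons[, 1], -1)))
    stop("exons must be sorted and non-overlapping")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  g <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = exons[1, 1], end = exons[nrow(exons), 2], exons = exons
  ), class = "gene_model")
  intr <- gene_introns(g)
  if (nrow(intr) > 0 && any(intr[, 2] - intr[, 1] < 20L))
    stop("all introns must be at least 20 bases long")
  g
}

#' @rdname gene_model
#' @param gene A `gene_model`.
#' @return For `gene_introns()`, a two-column matrix of intron intervals
#'   (0-based half-open), one row per gap between consecutive exons.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = utils::head(ex[, 2], -1), end = utils::tail(ex[, 1], -1))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

## Genomic blocks (0-based half-open, left to right) covered by an isoform:
## the exons plus any retained introns, merged into maximal runs.
.isoform_blocks <- function(gene, retained_introns) {
  ex <- gene$exons
  intr <- gene_introns(gene)
  iv <- ex
  if (length(retained_introns))
    iv <- rbind(iv, intr[retained_introns, , drop = FALSE])
  r <- IRanges::reduce(IRanges::IRanges(iv[, 1] + 1L, iv[, 2]))
  cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

## mRNA-sense sequence of an isoform given the chromosome sequence as a
## single character string.
.isoform_sequence <- function(chrom_seq, gene, blocks) {
  s <- paste0(substring(chrom_seq, blocks[, 1] + 1L, blocks[, 2]),
              collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

#' Simulate a transcriptome with spliced and intron-retained isoforms
#'
#' Generates a reference chromosome, `n_genes` multi-exon gene models, a
#' fully spliced isoform per gene plus (where the design gives a gene
#' non-zero retention) an isoform retaining one middle intron, and a truth
#' table with one row per read: sample, gene, isoform, orientation,
#' truncation and the error-free cDNA insert. Reads are drawn per
#' (condition, replicate, gene) with the design's mixing proportions, and
#' 5'-truncation follows the architecture's Beta distribution. The output is
#' deterministic for a fixed seed.
#'
#' @param n_genes Number of genes to simulate.
#' @param seed Integer seed; all randomness derives from it.
#' @param design A [condition_design()].
#' @param arch A [read_architecture()]; must carry at least
#'   `n_conditions * n_replicates` barcodes.
#' @param exon_range Integer range of exons per gene. Retained introns are
#'   always middle introns, so at least 4 exons are needed for retention to
#'   be visible to the terminal-trimmed pileup.
#' @return An object of class `sim_transcriptome`: a list with `reference`
#'   (a [Biostrings::DNAStringSet]), `genes` (named list of `gene_model`),
#'   `isoforms` (data.frame), `truth` (list of `reads`, `retention`,
#'   `sample_sheet` data.frames plus the seed), `design` and `arch`.
#' @export
#' @examples
#' sim <- simulate_transcriptome(
#'   n_genes = 2, seed = 1,
#'   design = condition_design(reads_per_gene = 20),
#'   arch = read_architecture(barcodes = default_barcodes(6))
#' )
#' head(sim$truth$reads)
simulate_transcriptome <- function(n_genes = 20L, seed = 1L,
                                   design = condition_design(),
                                   arch = read_architecture(),
                                   exon_range = c(4L, 6L)) {
  stopifnot(n_genes >= 1L, exon_range[1] >= 2L,
            exon_range[1] <= exon_range[2])
  stopifnot(inherits(design, "condition_design"),
            inherits(arch, "read_architecture"))
  conds <- names(design$conditions)
  n_samples <- length(conds) * design$n_replicates
  if (length(arch$barcodes) < n_samples)
    stop("architecture provides ", length(arch$barcodes),
         " barcodes but the design needs ", n_samples)
  set.seed(as.integer(seed))
  chrom <- "simchr1"

  ## --- gene structures -----------------------------------------------------
  genes <- vector("list", n_genes)
  pos <- 1000L
  for (g in seq_len(n_genes)) {
    ne <- if (exon_range[1] == exon_range[2]) exon_range[1] else
      sample(exon_range[1]:exon_range[2], 1L)
    elen <- sample(80:200, ne, replace = TRUE)
    ilen <- if (ne > 1L) sample(60:150, ne - 1L, replace = TRUE) else integer(0)
    starts <- pos + c(0L, cumsum(elen[-ne] + ilen))
    exons <- cbind(starts, starts + elen)
    gid <- sprintf("gene%03d", g)
    genes[[g]] <- gene_model(gid, chrom, sample(c("+", "-"), 1L), exons)
    pos <- genes[[g]]$end + 500L
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")

  ## --- reference sequence --------------------------------------------------
  ref_len <- pos + 500L
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                     collapse = "")
  reference <- Biostrings::DNAStringSet(structure(chrom_seq, names = chrom))

  ## --- per-gene, per-condition retention probabilities ---------------------
  retention <- matrix(design$background_retention, n_genes, length(conds),
                      dimnames = list(names(genes), conds))
  for (g in intersect(design$regulated_genes, seq_len(n_genes)))
    retention[g, ] <- vapply(design$conditions, `[[`, 0, "retained")

  ## --- isoforms ------------------------------------------------------------
  iso_rows <- list()
  iso_meta <- list()   # per isoform: gene, retained introns, blocks, mRNA
  for (g in seq_len(n_genes)) {
    gene <- genes[[g]]
    gid <- gene$gene_id
    ni <- nrow(gene_introns(gene))
    spl_id <- paste0(gid, ".spliced")
    blocks <- .isoform_blocks(gene, integer(0))
    iso_meta[[spl_id]] <- list(
      gene_id = gid, retained = integer(0), blocks = blocks,
      mrna = .isoform_sequence(chrom_seq, gene, blocks))
    iso_rows[[spl_id]] <- data.frame(
      isoform_id = spl_id, gene_id = gid, retained_introns = "",
      stringsAsFactors = FALSE)
    if (any(retention[g, ] > 0) && ni >= 1L) {
      k <- as.integer(ceiling(ni / 2))  # a middle intron where possible
      ret_id <- sprintf("%s.ret%d", gid, k)
      blocks <- .isoform_blocks(gene, k)
      iso_meta[[ret_id]] <- list(
        gene_id = gid, retained = k, blocks = blocks,
        mrna = .isoform_sequence(chrom_seq, gene, blocks))
      iso_rows[[ret_id]] <- data.frame(
        isoform_id = ret_id, gene_id = gid,
        retained_introns = as.character(k), stringsAsFactors = FALSE)
    }
  }
  isoforms <- do.call(rbind, c(iso_rows, list(make.row.names = FALSE)))

  ## --- sample sheet --------------------------------------------------------
  sample_sheet <- expand.grid(replicate = seq_len(design$n_replicates),
                              condition = conds, stringsAsFactors = FALSE)
  sample_sheet <- sample_sheet[, c("condition", "replicate")]
  sample_sheet$sample_id <- paste0(sample_sheet$condition, "_",
                                   sample_sheet$replicate)
  sample_sheet$barcode_id <- names(arch$barcodes)[seq_len(n_samples)]
  sample_sheet$barcode <- unname(arch$barcodes[seq_len(n_samples)])

  ## --- truth reads ---------------------------------------------------------
  blocks_of <- lapply(iso_meta, `[[`, "blocks")
  mrna_of <- vapply(iso_meta, `[[`, "", "mrna")
  chunk <- list(); ci <- 0L
  for (si in seq_len(nrow(sample_sheet))) {
    cond <- sample_sheet$condition[si]
    for (g in seq_len(n_genes)) {
      gene <- genes[[g]]
      gid <- gene$gene_id
      n <- design$reads_per_gene
      p <- retention[g, cond]
      ret_id <- grep(paste0("^", gid, "\\.ret"), names(iso_meta), value = TRUE)
      has_ret <- length(ret_id) == 1L && p > 0
      n_ret <- if (!has_ret) 0L else if (design$exact_mix)
        as.integer(round(p * n)) else rbinom(1L, n, p)
      iso <- c(rep(ret_id, n_ret),
               rep(paste0(gid, ".spliced"), n - n_ret))
      L <- nchar(mrna_of[iso])
      frac <- if (is.null(arch$truncation)) rep(1, n) else
        rbeta(n, arch$truncation[1], arch$truncation[2])
      keep <- pmin(L, pmax(50L, as.integer(ceiling(frac * L))))
      orient <- ifelse(runif(n) < arch$forward_prob, "forward", "reverse")
      ci <- ci + 1L
      chunk[[ci]] <- data.frame(
        barcode_id = sample_sheet$barcode_id[si],
        sample_id = sample_sheet$sample_id[si],
        condition = cond, replicate = sample_sheet$replicate[si],
        gene_id = gid, isoform_id = iso, orientation = orient,
        keep_len = keep,
        insert = substring(mrna_of[iso], L - keep + 1L, L),
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, c(chunk, list(make.row.names = FALSE)))
  reads <- cbind(read_id = sprintf("read_%07d", seq_len(nrow(reads))), reads,
                 stringsAsFactors = FALSE)

  ## --- retention truth table ----------------------------------------------
  ret_rows <- list()
  for (g in seq_len(n_genes)) {
    gid <- genes[[g]]$gene_id
    ret_iso <- iso_meta[[grep(paste0("^", gid, "\\.ret"),
                              names(iso_meta), value = TRUE)[1]]]
    if (is.null(ret_iso)) next
    for (cond in conds)
      ret_rows[[paste(gid, cond)]] <- data.frame(
        gene_id = gid, intron_index = ret_iso$retained,
        condition = cond, p_retained = retention[g, cond],
        stringsAsFactors = FALSE)
  }
  retention_tab <- if (length(ret_rows))
    do.call(rbind, c(ret_rows, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(0), intron_index = integer(0),
                  condition = character(0), p_retained = numeric(0))

  structure(list(
    reference = reference, genes = genes, isoforms = isoforms,
    iso_meta = iso_meta,
    truth = list(reads = reads, retention = retention_tab,
                 sample_sheet = sample_sheet, seed = as.integer(seed)),
    design = design, arch = arch
  ), class = "sim_transcriptome")
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat(sprintf(paste0("<sim_transcriptome> %d genes, %d isoforms, ",
                     "%d samples, %d reads (seed %d)\n"),
              length(x$genes), nrow(x$isoforms),
              nrow(x$truth$sample_sheet), nrow(x$truth$reads),
              x$truth$seed))
  invisible(x)
}
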