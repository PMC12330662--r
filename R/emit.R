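## Substitution (and optional indel) errors on a vector of sequences.
## Caller is responsible for seeding the RNG.
.mutate_seqs <- function(seqs, sub_rate, indel_rate = 0) {
  if (sub_rate <= 0 && indel_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (sub_rate > 0) {
      nsub <- rbinom(1L, n, sub_rate)
      if (nsub > 0) {
        pos <- sample.int(n, nsub)
        for (p in pos) ch[p] <- sample(bases[bases != ch[p]], 1L)
      }
    }
    if (indel_rate > 0) {
      ndel <- rbinom(1L, length(ch), indel_rate / 2)
      if (ndel > 0 && ndel < length(ch))
        ch <- ch[-sample.int(length(ch), ndel)]
      nins <- rbinom(1L, length(ch), indel_rate / 2)
      if (nins > 0)
        for (p in sort(sample.int(length(ch), nins), decreasing = TRUE))
          ch <- append(ch, sample(bases, 1L), after = p)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Emit raw barcoded reads from a simulation
#'
#' Assembles, for every read in the truth table, the forward layout
#' `[barcode][poly-T][revcomp(cDNA insert)][revcomp(CP)]`, reverse-complements
#' reads whose truth orientation is `"reverse"`, and injects substitution
#' (and optionally indel) errors at the architecture's rates.
#'
#' @param sim A [simulate_transcriptome()] result.
#' @param seed Seed for poly-T lengths and error injection; defaults to a
#'   fixed offset of the simulation seed so repeated calls are byte-identical.
#' @return A data.frame with columns `read_id` and `sequence`.
#' @seealso [write_fastq()]
#' @export
emit_raw_reads <- function(sim, seed = sim$truth$seed + 1000003L) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  reads <- sim$truth$reads
  arch <- sim$arch
  set.seed(as.integer(seed))
  n <- nrow(reads)
  rng <- arch$polyt_len
  plen <- if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(rng[1]:rng[2], n, replace = TRUE)
  bc <- unname(arch$barcodes[reads$barcode_id])
  fwd <- paste0(bc, strrep("T", plen), revcomp(reads$insert),
                revcomp(arch$cp))
  isrev <- reads$orientation == "reverse"
  fwd[isrev] <- revcomp(fwd[isrev])
  data.frame(read_id = reads$read_id,
             sequence = .mutate_seqs(fwd, arch$error_rate, arch$indel_rate),
             stringsAsFactors = FALSE)
}

#' Emit spliced alignments from a simulation
#'
#' Constructs, for every read in the truth table, the alignment record a
#' splice-aware aligner would report: `M` runs over the isoform's genomic
#' blocks and `N` runs over the introns it splices out, shortened from the
#' transcript 5' end by the read's truncation. Alignments are always recorded
#' in reference orientation (the CIGAR is on the forward genomic strand);
#' reads of minus-strand genes carry the reverse flag.
#'
#' @param sim A [simulate_transcriptome()] result.
#' @return A data.frame with columns `read_id`, `flag`, `chrom`, `pos`
#'   (0-based leftmost aligned base), `mapq`, `cigar` and `sequence`
#'   (reference-oriented).
#' @seealso [write_sam()]
#' @export
emit_alignments <- function(sim) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  reads <- sim$truth$reads
  if (!all(reads$gene_id %in% names(sim$genes)))
    stop("truth table names a gene absent from the gene models")
  chrom_seq <- as.character(sim$reference)
  meta <- sim$iso_meta
  offs <- lapply(meta, function(m) {
    w <- m$blocks[, 2] - m$blocks[, 1]
    list(off = cumsum(c(0L, w)), L = sum(w))
  })
  n <- nrow(reads)
  pos <- integer(n); cig <- character(n); sq <- character(n); fl <- integer(n)
  for (i in seq_len(n)) {
    iso <- reads$isoform_id[i]
    m <- meta[[iso]]
    if (is.null(m)) stop("unknown isoform: ", iso)
    gene <- sim$genes[[m$gene_id]]
    off <- offs[[iso]]$off
    L <- offs[[iso]]$L
    K <- reads$keep_len[i]
    ab <- if (gene$strand == "+") c(L - K, L) else c(0L, K)
    blocks <- m$blocks
    nb <- nrow(blocks)
    cs <- ce <- integer(0)
    for (k in seq_len(nb)) {
      lo <- max(ab[1], off[k]); hi <- min(ab[2], off[k + 1])
      if (hi > lo) {
        cs <- c(cs, blocks[k, 1] + (lo - off[k]))
        ce <- c(ce, blocks[k, 1] + (hi - off[k]))
      }
    }
    runs <- character(2L * length(cs) - 1L)
    runs[seq(1, length(runs), by = 2)] <- paste0(ce - cs, "M")
    if (length(cs) > 1L)
      runs[seq(2, length(runs), by = 2)] <-
        paste0(cs[-1] - ce[-length(ce)], "N")
    pos[i] <- cs[1]
    cig[i] <- paste(runs, collapse = "")
    sq[i] <- paste0(substring(chrom_seq[gene$chrom], cs + 1L, ce),
                    collapse = "")
    fl[i] <- if (gene$strand == "-") 16L else 0L
  }
  data.frame(read_id = reads$read_id, flag = fl,
             chrom = vapply(reads$gene_id,
                            function(g) sim$genes[[g]]$chrom, ""),
             pos = pos, mapq = 60L, cigar = cig, sequence = sq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads as FASTQ
#'
#' @param reads Data.frame with `read_id` and `sequence` columns (as from
#'   [emit_raw_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(structure(reads$sequence,
                                          names = reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write alignments as SAM
#'
#' @param aln Alignment data.frame as produced by [emit_alignments()].
#' @param seqlengths Named integer vector of reference sequence lengths.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  aln$read_id, aln$flag, aln$chrom, aln$pos + 1L,
                  aln$mapq, aln$cigar, aln$sequence)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read spliced alignments from SAM/BAM
#'
#' Reads primary alignments (secondary, supplementary and unmapped records
#' are dropped) and computes each read's aligned fraction from its CIGAR.
#' SAM files are converted on the fly through [Rsamtools::asBam()].
#'
#' @param path A `.sam` or `.bam` file.
#' @return Data.frame with `read_id`, `flag`, `chrom`, `pos` (0-based),
#'   `cigar` and `aligned_fraction`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos) & bitwAnd(b$flag, 0x904L) == 0L
  data.frame(read_id = b$qname[keep], flag = b$flag[keep],
             chrom = as.character(b$rname[keep]), pos = b$pos[keep] - 1L,
             cigar = b$cigar[keep],
             aligned_fraction = aligned_fraction(b$cigar[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write gene models as GTF
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path (`.gtf`).
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    ne <- nrow(g$exons)
    S4Vectors::DataFrame(
      chrom = g$chrom,
      start = c(g$start, g$exons[, 1]) + 1L,
      end = c(g$end, g$exons[, 2]),
      strand = g$strand,
      type = c("gene", rep("exon", ne)),
      gene_id = g$gene_id,
      transcript_id = c(NA, rep(paste0(g$gene_id, ".t1"), ne)))
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$type <- tab$type
  gr$gene_id <- tab$gene_id
  gr$transcript_id <- tab$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF/GFF
#'
#' Reconstructs [gene_model()] objects from the exon records of an
#' annotation file, grouped by `gene_id`.
#'
#' @param path A `.gtf`/`.gff` file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0) stop("no exon records in ", path)
  split_ex <- S4Vectors::split(ex, ex$gene_id)
  genes <- lapply(names(split_ex), function(gid) {
    e <- BiocGenerics::sort(split_ex[[gid]])
    gene_model(gid, as.character(GenomicRanges::seqnames(e))[1],
               as.character(BiocGenerics::strand(e))[1],
               cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e)))
  })
  names(genes) <- names(split_ex)
  genes
}

#' Write a full simulation bundle to disk
#'
#' Materialises a simulation as the standard file formats the pipeline
#' consumes: reference FASTA, annotation GTF, raw reads FASTQ, spliced
#' alignments SAM, sample sheet / barcode TSVs, truth tables, and a YAML
#' config recording the seed and all rates.
#'
#' @param sim A [simulate_transcriptome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  Biostrings::writeXStringSet(sim$reference, f("reference.fa"))
  write_gene_models(sim$genes, f("annotation.gtf"))
  write_fastq(emit_raw_reads(sim), f("reads.fastq"))
  aln <- emit_alignments(sim)
  seqlen <- structure(Biostrings::width(sim$reference),
                      names = names(sim$reference))
  write_sam(aln, seqlen, f("alignments.sam"))
  .write_tsv(sim$truth$sample_sheet, f("sample_sheet.tsv"))
  .write_tsv(data.frame(barcode_id = names(sim$arch$barcodes),
                        sequence = unname(sim$arch$barcodes)),
             f("barcodes.tsv"))
  .write_tsv(sim$truth$reads, f("truth_reads.tsv"))
  .write_tsv(sim$truth$retention, f("truth_retention.tsv"))
  yaml::write_yaml(list(
    seed = sim$truth$seed,
    n_genes = length(sim$genes),
    conditions = lapply(sim$design$conditions, as.list),
    n_replicates = sim$design$n_replicates,
    reads_per_gene = sim$design$reads_per_gene,
    error_rate = sim$arch$error_rate,
    indel_rate = sim$arch$indel_rate,
    forward_prob = sim$arch$forward_prob,
    cp = sim$arch$cp), f("sim_config.yaml"))
  out <- c(reference = f("reference.fa"), annotation = f("annotation.gtf"),
           reads = f("reads.fastq"), alignments = f("alignments.sam"),
           sample_sheet = f("sample_sheet.tsv"), barcodes = f("barcodes.tsv"),
           truth_reads = f("truth_reads.tsv"),
           truth_retention = f("truth_retention.tsv"),
           config = f("sim_config.yaml"))
  invisible(out)
}
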