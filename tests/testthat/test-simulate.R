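small_arch <- function(...) {
  read_architecture(barcodes = default_barcodes(6), ...)
}

test_that("simulation is deterministic for a fixed seed", {
  design <- condition_design(reads_per_gene = 30)
  s1 <- simulate_transcriptome(n_genes = 3, seed = 42, design = design,
                               arch = small_arch())
  s2 <- simulate_transcriptome(n_genes = 3, seed = 42, design = design,
                               arch = small_arch())
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(s1$truth$reads, s2$truth$reads)
  expect_identical(emit_raw_reads(s1), emit_raw_reads(s2))
  expect_identical(emit_alignments(s1), emit_alignments(s2))
  s3 <- simulate_transcriptome(n_genes = 3, seed = 43, design = design,
                               arch = small_arch())
  expect_false(identical(s1$truth$reads, s3$truth$reads))
})

test_that("simulated files are byte-identical across runs of one seed", {
  design <- condition_design(reads_per_gene = 10)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_simulation(simulate_transcriptome(2, 9, design, small_arch()),
                         d1)
  f2 <- write_simulation(simulate_transcriptome(2, 9, design, small_arch()),
                         d2)
  h1 <- unname(tools::md5sum(unname(f1)))
  h2 <- unname(tools::md5sum(unname(f2)))
  expect_identical(h1, h2)
})

test_that("a degenerate all-spliced mixture yields only spliced reads", {
  design <- condition_design(
    conditions = list(ctrl = c(spliced = 1, retained = 0)),
    reads_per_gene = 50)
  sim <- simulate_transcriptome(n_genes = 1, seed = 1, design = design,
                                arch = small_arch(),
                                exon_range = c(2L, 2L))
  expect_equal(nrow(gene_introns(sim$genes[[1]])), 1L)
  expect_true(all(grepl("\\.spliced$", sim$truth$reads$isoform_id)))
})

test_that("invalid mixing proportions are rejected with a message", {
  expect_error(
    condition_design(conditions = list(a = c(spliced = 0.6,
                                             retained = 0.6))),
    "sum to 1")
  expect_error(
    condition_design(conditions = list(a = c(bad = 1))),
    "spliced")
})

test_that("empirical retained fraction matches the configured probability", {
  p <- 0.3
  n <- 10000L
  design <- condition_design(
    conditions = list(only = c(spliced = 1 - p, retained = p)),
    n_replicates = 1L, reads_per_gene = n)
  sim <- simulate_transcriptome(n_genes = 1, seed = 77, design = design,
                                arch = small_arch())
  frac <- mean(grepl("\\.ret", sim$truth$reads$isoform_id))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("truth, FASTQ and alignment record counts agree", {
  sim <- simulate_transcriptome(2, 3, condition_design(reads_per_gene = 20),
                                small_arch())
  reads <- emit_raw_reads(sim)
  aln <- emit_alignments(sim)
  expect_identical(nrow(reads), nrow(sim$truth$reads))
  expect_identical(nrow(aln), nrow(sim$truth$reads))
  expect_identical(sort(reads$read_id), sort(sim$truth$reads$read_id))
  expect_false(anyDuplicated(reads$read_id) > 0)
})

test_that("alignments reconstruct the isoform structure from the gene model", {
  design <- condition_design(
    conditions = list(ctrl = c(spliced = 0.5, retained = 0.5)),
    n_replicates = 1L, reads_per_gene = 60)
  sim <- simulate_transcriptome(n_genes = 2, seed = 5, design = design,
                                arch = small_arch(truncation = NULL))
  aln <- emit_alignments(sim)
  tr <- sim$truth$reads
  for (g in names(sim$genes)) {
    gene <- sim$genes[[g]]
    ex <- gene$exons
    intr <- gene_introns(gene)
    ## full-length spliced read: M over exons, N over introns, at gene start
    spliced_cigar <- paste0(paste0(ex[, 2] - ex[, 1], "M")[1],
      paste0(paste0(intr[, 2] - intr[, 1], "N"),
             paste0(ex[-1, 2] - ex[-1, 1], "M"), collapse = ""))
    i <- which(tr$gene_id == g & grepl("spliced", tr$isoform_id))
    expect_true(all(aln$cigar[i] == spliced_cigar))
    expect_true(all(aln$pos[i] == gene$start))
    ## retained read: the retained intron is absorbed into one M run
    j <- which(tr$gene_id == g & grepl("\\.ret", tr$isoform_id))
    if (length(j)) {
      k <- as.integer(sub(".*\\.ret", "", tr$isoform_id[j[1]]))
      runs <- strsplit(gsub("([MN])", "\\1 ", aln$cigar[j[1]]), " ")[[1]]
      nN <- sum(grepl("N", runs))
      expect_identical(nN, nrow(intr) - 1L)
      merged <- sum(ex[k:(k + 1), 2] - ex[k:(k + 1), 1]) +
        (intr[k, 2] - intr[k, 1])
      expect_true(paste0(merged, "M") %in% runs)
    }
  }
})

test_that("5'-truncation shortens alignments from the transcript 5' end", {
  design <- condition_design(
    conditions = list(ctrl = c(spliced = 1, retained = 0)),
    n_replicates = 1L, reads_per_gene = 200)
  sim <- simulate_transcriptome(n_genes = 1, seed = 8, design = design,
                                arch = small_arch())
  aln <- emit_alignments(sim)
  gene <- sim$genes[[1]]
  tr <- sim$truth$reads
  fw <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  if (gene$strand == "+") {
    ## 3' anchor is the genomic right end: all alignments end there
    expect_true(all(aln$pos + fw == gene$end))
    ## a read truncated past the first exon starts beyond it
    short <- tr$keep_len < sum(gene$exons[-1, 2] - gene$exons[-1, 1])
    if (any(short))
      expect_true(all(aln$pos[short] >= gene$exons[2, 1]))
  } else {
    expect_true(all(aln$pos == gene$start))
  }
  ## truncated reads never align more transcript than they kept
  expect_true(all(nchar(aln$sequence) == tr$keep_len))
})

test_that("error-free reads carry the exact barcode and layout", {
  sim <- simulate_transcriptome(
    1, 2,
    condition_design(reads_per_gene = 20),
    small_arch(error_rate = 0, forward_prob = 1, truncation = NULL))
  reads <- emit_raw_reads(sim)
  bc <- sim$arch$barcodes[sim$truth$reads$barcode_id]
  expect_true(all(substr(reads$sequence, 1, 16) == bc))
  expect_true(all(substr(reads$sequence,
                         nchar(reads$sequence) - nchar(sim$arch$cp) + 1,
                         nchar(reads$sequence)) == revcomp(sim$arch$cp)))
})

test_that("substitution errors hit barcodes at the expected rate", {
  sim <- simulate_transcriptome(
    2, 6, condition_design(reads_per_gene = 200),
    small_arch(error_rate = 0.02, forward_prob = 1))
  reads <- emit_raw_reads(sim)
  bc <- unname(sim$arch$barcodes[sim$truth$reads$barcode_id])
  mm <- vapply(seq_len(nrow(reads)), function(i)
    sum(strsplit(substr(reads$sequence[i], 1, 16), "")[[1]] !=
          strsplit(bc[i], "")[[1]]), 0L)
  ## Binomial(16, 0.02) per read: mean 0.32
  expect_lt(abs(mean(mm) - 0.32), 0.05)
})
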