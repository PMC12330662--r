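CP <- "AAGCAGTGGTATCAACGCAGAGT"

test_that("poly-T detection finds simple tracts and honours the 90% rule", {
  r <- paste0("AAAA", strrep("T", 12), "CCGG")
  hit <- find_polyt(r)
  expect_equal(hit[c("start", "end")], list(start = 5L, end = 16L))
  expect_equal(hit$orientation, "forward")

  expect_null(find_polyt("ACGACGACGACGACGACGACG"))

  ## one C inside 12 positions: 11/12 = 0.917 >= 0.9
  r2 <- paste0("GGGG", strrep("T", 5), "C", strrep("T", 6), "GGGG")
  hit2 <- find_polyt(r2)
  expect_false(is.null(hit2))
  expect_gte(hit2$length, 10)

  ## tract on the reverse complement is reported as reverse orientation
  r3 <- revcomp(paste0("AAAACCGG", strrep("T", 14), "GGCC"))
  expect_equal(find_polyt(r3)$orientation, "reverse")
})

test_that("poly-T detection matches the all-windows oracle", {
  set.seed(101)
  for (i in 1:150) {
    n <- sample(30:120, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.4)), collapse = "")
    if (runif(1) < 0.5) {
      ins <- sample(n - 1, 1)
      s <- paste0(substr(s, 1, ins), strrep("T", sample(8:20, 1)),
                  substr(s, ins + 1, n))
    }
    got <- nanopsi:::.polyt_window_cpp(s, 10L, 0.9)
    want <- oracle_polyt(s, 10L, 0.9)
    if (is.null(want)) {
      expect_equal(got$length, 0)
    } else {
      expect_equal(got[c("start", "end", "length")], want,
                   info = paste("seq:", s))
    }
  }
})

test_that("common-primer search reports loci within tolerance only", {
  read <- paste0("GGGGACCC", CP, "TTAACCGG")
  hit <- find_common_primer(read, CP)
  expect_equal(hit$distance, 0)
  expect_equal(substr(read, hit$start, hit$end), CP)

  ## two substitutions: found at distance 2
  cp2 <- CP
  substr(cp2, 3, 3) <- "T"; substr(cp2, 10, 10) <- "C"
  hit2 <- find_common_primer(paste0("GGGGACCC", cp2, "TTAACCGG"), CP)
  expect_equal(hit2$distance, 2)

  ## four edits exceed the tolerance of 3
  cp4 <- CP
  substr(cp4, 1, 1) <- "C"; substr(cp4, 5, 5) <- "C"
  substr(cp4, 9, 9) <- "T"; substr(cp4, 13, 13) <- "A"
  expect_null(find_common_primer(paste0("GGGGACCC", cp4, "TTAACCGG"), CP))
})

test_that("infix edit distance agrees with a full-DP oracle", {
  set.seed(55)
  for (i in 1:120) {
    pat <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1),
                        replace = TRUE), collapse = "")
    txt <- paste(sample(c("A", "C", "G", "T"), sample(20:80, 1),
                        replace = TRUE), collapse = "")
    got <- nanopsi:::.edit_locate_cpp(pat, txt)
    expect_identical(got$distance, oracle_infix_dist(pat, txt),
                     info = paste(pat, txt))
  }
})

test_that("barcode assignment follows the anchored geometry rules", {
  bcs <- default_barcodes(4)
  insert <- paste(rep(c("G", "C", "A"), 40), collapse = "")
  mk <- function(bc) paste0(bc, strrep("T", 15), insert, revcomp(CP))

  ## perfect barcode adjacent to the poly-T: assigned at distance 0
  a <- assign_barcode(mk(bcs[["BC02"]]), bcs, cp = CP)
  expect_equal(a$status, "assigned")
  expect_equal(a$barcode_id, "BC02")
  expect_equal(a$distance, 0L)
  expect_equal(a$orientation, "forward")

  ## same read in reverse orientation
  ar <- assign_barcode(revcomp(mk(bcs[["BC03"]])), bcs, cp = CP)
  expect_equal(ar$status, "assigned")
  expect_equal(ar$barcode_id, "BC03")
  expect_equal(ar$orientation, "reverse")

  ## barcode on the wrong side of the poly-T: none_found
  wrong <- paste0("GGCCGGCCGGCCGGCC", strrep("T", 15), bcs[["BC01"]],
                  insert, revcomp(CP))
  expect_equal(assign_barcode(wrong, bcs, cp = CP)$status, "none_found")

  ## adversarial barcodes within 3 edits of each other: multiple_found
  adv <- c(X = "AAAAAAAACCCCGGGG", Y = "AAAAAAAACCCCGGTT")
  m <- assign_barcode(paste0(adv[["X"]], strrep("T", 15), insert,
                             revcomp(CP)), adv, cp = CP)
  expect_equal(m$status, "multiple_found")

  ## conflicting anchor orientations disqualify the read: here the CP is
  ## embedded in the orientation opposite to the poly-T's
  confl <- paste0(bcs[["BC01"]], strrep("T", 15), insert, CP)
  expect_equal(assign_barcode(confl, bcs, cp = CP)$status, "none_found")
})

test_that("trimming removes all primer structure and canonicalises", {
  bcs <- default_barcodes(3)
  insert <- paste(rep(c("G", "A", "C", "A"), 30), collapse = "")
  read <- paste0(bcs[["BC01"]], strrep("T", 15), insert, revcomp(CP))
  a <- assign_barcode(read, bcs, cp = CP)
  tr <- trim_read(read, a)
  expect_true(tr$trimmed)
  ## canonical orientation is mRNA sense: the insert region of the forward
  ## layout is revcomp(cDNA), so trimming returns its reverse complement
  expect_equal(tr$sequence, revcomp(insert))

  ## reverse-orientation read trims to the same canonical sequence
  a2 <- assign_barcode(revcomp(read), bcs, cp = CP)
  expect_equal(trim_read(revcomp(read), a2)$sequence, revcomp(insert))

  ## unassigned reads come back unmodified and flagged
  noanchor <- "ACGTACGTAGCATCGATCGAGCGCATATA"
  a3 <- assign_barcode(noanchor, bcs, cp = CP)
  expect_equal(a3$status, "none_found")
  tr3 <- trim_read(noanchor, a3)
  expect_false(tr3$trimmed)
  expect_equal(tr3$sequence, noanchor)
})

test_that("trimmed inserts of error-injected reads match truth closely", {
  sim <- simulate_transcriptome(
    2, 21, condition_design(reads_per_gene = 25),
    read_architecture(barcodes = default_barcodes(6), error_rate = 0.02))
  reads <- emit_raw_reads(sim)
  rep <- demux_reads(reads, sim$arch$barcodes, cp = sim$arch$cp)
  ok <- which(rep$status == "assigned")
  expect_gt(length(ok), 0.95 * nrow(reads))
  ident <- vapply(ok, function(i) {
    a <- rep$trimmed_sequence[i]; b <- sim$truth$reads$insert[i]
    1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
  }, 0)
  expect_gt(mean(ident >= 0.95), 0.95)
})

test_that("every read gets exactly one demultiplexing status", {
  sim <- simulate_transcriptome(
    1, 31, condition_design(reads_per_gene = 30),
    read_architecture(barcodes = default_barcodes(6), error_rate = 0.05))
  reads <- emit_raw_reads(sim)
  rep <- demux_reads(reads, sim$arch$barcodes, cp = sim$arch$cp)
  expect_identical(nrow(rep), nrow(reads))
  expect_true(all(rep$status %in% c("assigned", "none_found",
                                    "multiple_found")))
})

test_that("error-free demultiplexing has perfect precision and recall", {
  sim <- simulate_transcriptome(
    2, 13, condition_design(reads_per_gene = 40),
    read_architecture(barcodes = default_barcodes(6), error_rate = 0))
  reads <- emit_raw_reads(sim)
  rep <- demux_reads(reads, sim$arch$barcodes, cp = sim$arch$cp)
  expect_true(all(rep$status == "assigned"))
  expect_identical(rep$barcode_id, sim$truth$reads$barcode_id)
  expect_true(all(rep$distance == 0L))
})
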