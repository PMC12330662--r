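test_that("coverage mask applies per-sample and per-condition floors", {
  spanning <- rbind(c(4, 100, 100),    # one sample below 5
                    c(19, 19, 19),     # mean below 20
                    c(25, 25, 25),     # fine
                    c(5, 20, 100))     # min exactly 5, mean > 20
  m <- coverage_mask(spanning, conditions = rep("a", 3))
  expect_equal(m, c(FALSE, FALSE, TRUE, TRUE))

  ## with two conditions, every condition's mean must reach 20
  m2 <- coverage_mask(cbind(c(100, 100), c(100, 100), c(100, 15),
                            c(100, 15)),
                      conditions = c("a", "a", "b", "b"))
  expect_equal(m2, c(TRUE, FALSE))
})

test_that("the cumulative-average scan segments step signals exactly", {
  ## constant signal: one region
  r1 <- segment_psi(rep(1, 500))
  expect_equal(r1, data.frame(start = 0L, end = 500L))

  ## a step from 1.0 to 0.0: boundary exactly at the step
  r2 <- segment_psi(c(rep(1, 200), rep(0, 100)))
  expect_equal(r2$start, c(0L, 200L))
  expect_equal(r2$end, c(200L, 300L))

  ## alternating 0.95/0.90 never deviates by more than 0.1: one region
  r3 <- segment_psi(rep(c(0.95, 0.90), 100))
  expect_equal(nrow(r3), 1L)

  ## masked positions are skipped without closing the region
  psi <- rep(1, 100)
  mask <- rep(TRUE, 100); mask[40:60] <- FALSE
  r4 <- segment_psi(psi, mask)
  expect_equal(nrow(r4), 1L)

  ## empty mask yields no regions
  expect_equal(nrow(segment_psi(rep(1, 10), rep(FALSE, 10))), 0L)

  ## genomic offset shifts the reported intervals
  r5 <- segment_psi(rep(1, 10), offset = 1000L)
  expect_equal(r5$start, 1000L)
})

test_that("segmentation is idempotent on the per-region mean signal", {
  set.seed(31)
  psi <- c(rep(0.95, 120), rep(0.35, 80), rep(0.9, 150)) +
    runif(350, -0.02, 0.02)
  r <- segment_psi(psi)
  smooth <- numeric(length(psi))
  for (i in seq_len(nrow(r))) {
    idx <- (r$start[i] + 1L):r$end[i]
    smooth[idx] <- mean(psi[idx])
  }
  expect_equal(segment_psi(smooth)[, c("start", "end")],
               r[, c("start", "end")])
})

test_that("regions retained in no condition are excluded", {
  regions <- data.frame(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  psi <- rbind(c(0.02, 0.03),   # never retained: dropped
               c(0.02, 0.60),   # retained in one condition: kept
               c(0.05, 0.01))   # exactly at the floor: kept
  kept <- filter_regions(regions, psi)
  expect_equal(kept$start, c(100L, 200L))
})

test_that("region summaries average and round half-to-even", {
  pl <- function(spl, spa) structure(
    list(gene_id = "g", chrom = "c", start = 0L,
         spliced_in = as.integer(spl), spanning = as.integer(spa)),
    class = "splice_pileup")
  ## constant counts pass through
  s1 <- summarize_region(data.frame(start = 0L, end = 3L),
                         list(a = pl(c(10, 10, 10), c(20, 20, 20))))
  expect_equal(s1$k, 10L); expect_equal(s1$n, 20L)
  ## means of 10.5 and 20.5 round to even: 10 and 20
  s2 <- summarize_region(data.frame(start = 0L, end = 2L),
                         list(a = pl(c(10, 11), c(20, 21))))
  expect_equal(s2$k, 10L); expect_equal(s2$n, 20L)
  ## a single-position region passes its counts through
  s3 <- summarize_region(data.frame(start = 1L, end = 2L),
                         list(a = pl(c(3, 7, 9), c(5, 11, 13))))
  expect_equal(s3$k, 7L); expect_equal(s3$n, 11L)
})

test_that("noise-free simulations recover intron boundaries within 1 bp", {
  design <- condition_design(
    conditions = list(a = c(spliced = 0.5, retained = 0.5),
                      b = c(spliced = 0.5, retained = 0.5)),
    n_replicates = 3L, reads_per_gene = 60L,
    background_retention = 0.5, exact_mix = TRUE)
  sim <- simulate_transcriptome(
    4, 23, design,
    read_architecture(barcodes = default_barcodes(6), error_rate = 0,
                      truncation = NULL))
  aln <- emit_alignments(sim)
  aln$sample_id <- sim$truth$reads$sample_id
  pls <- gene_pileups(aln, sim$genes)
  for (g in names(sim$genes)) {
    gene <- sim$genes[[g]]
    pl <- lapply(pls, `[[`, g)
    spl <- vapply(pl, `[[`, integer(gene$end - gene$start), "spliced_in")
    spa <- vapply(pl, `[[`, integer(gene$end - gene$start), "spanning")
    mask <- coverage_mask(spa, sim$truth$sample_sheet$condition)
    regions <- segment_psi(rowSums(spl) / rowSums(spa), mask,
                           offset = gene$start)
    bounds <- sort(unique(c(regions$start, regions$end)))
    intr <- gene_introns(gene)
    k <- sim$truth$retention$intron_index[
      sim$truth$retention$gene_id == g][1]
    ## interior intron boundaries carry a %SI step > 0.1 and must be hit;
    ## boundaries of terminal-trimmed introns coincide with coverage edges
    for (b in c(intr[k, 1], intr[k, 2]))
      expect_lte(min(abs(bounds - b)), 1L)
  }
})
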