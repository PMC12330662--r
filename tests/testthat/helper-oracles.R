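# Independent brute-force oracles, deliberately implemented with different
# mechanics than the package (matrix DP, full window enumeration, per-base
# expansion) so the two routes can disagree.

## Infix (semi-global) Levenshtein distance by full DP over a matrix.
oracle_infix_dist <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p); n <- length(t)
  prev <- rep(0L, n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1] <- i
    for (j in seq_len(n))
      cur[j + 1L] <- min(prev[j] + (p[i] != t[j]), prev[j + 1L] + 1L,
                         cur[j] + 1L)
    prev <- cur
  }
  min(prev)
}

## Longest T-dominated window by enumerating every (i, j) pair.
oracle_polyt <- function(s, min_run = 10L, frac = 0.9) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  isT <- ch == "T"
  cnt <- cumsum(isT)
  best_len <- 0L; bi <- NA_integer_; bj <- NA_integer_
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      tc <- cnt[j] - if (i > 1L) cnt[i - 1L] else 0L
      if (tc >= frac * len && len > best_len) {
        best_len <- len; bi <- i; bj <- j
      }
    }
  }
  if (is.na(bi) || best_len < min_run) return(NULL)
  while (bi <= bj && !isT[bi]) bi <- bi + 1L
  while (bj >= bi && !isT[bj]) bj <- bj - 1L
  if (bj - bi + 1L < min_run) return(NULL)
  list(start = bi, end = bj, length = bj - bi + 1L)
}

## Parse a CIGAR with a regex (independent of GenomicAlignments).
oracle_cigar_runs <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = substring(m, nchar(m)),
             len = as.integer(substring(m, 1, nchar(m) - 1L)))
}

## Per-base pileup oracle: expand the CIGAR to a per-reference-base class
## vector, merge short runs via rle relabelling, drop terminal runs, and
## accumulate base by base.
oracle_pileup <- function(aln, gene, min_run = 10L) {
  w <- gene$end - gene$start
  spl <- integer(w); spa <- integer(w)
  for (r in seq_len(nrow(aln))) {
    runs <- oracle_cigar_runs(aln$cigar[r])
    cls <- character(0)
    for (q in seq_len(nrow(runs))) {
      if (runs$op[q] %in% c("M", "=", "X"))
        cls <- c(cls, rep("present", runs$len[q]))
      else if (runs$op[q] %in% c("N", "D"))
        cls <- c(cls, rep("absent", runs$len[q]))
    }
    if (length(cls) == 0) next
    repeat {
      rl <- rle(cls)
      if (length(rl$lengths) <= 1L) break
      short <- which(rl$lengths < min_run)
      if (length(short) == 0) break
      i <- short[1]
      tgt <- if (i == 1L) rl$values[2] else rl$values[i - 1L]
      off <- cumsum(c(0L, rl$lengths))
      cls[(off[i] + 1L):off[i + 1L]] <- tgt
    }
    rl <- rle(cls)
    if (length(rl$lengths) <= 2L) next
    off <- cumsum(c(0L, rl$lengths))
    for (q in 2:(length(rl$lengths) - 1L)) {
      for (b in (off[q] + 1L):off[q + 1L]) {
        gpos <- aln$pos[r] + b - 1L   # 0-based genomic position
        if (gpos < gene$start || gpos >= gene$end) next
        idx <- gpos - gene$start + 1L
        spa[idx] <- spa[idx] + 1L
        if (rl$values[q] == "present") spl[idx] <- spl[idx] + 1L
      }
    }
  }
  list(spliced_in = spl, spanning = spa)
}

## Exhaustive overlap-ratio scorer over every annotation.
oracle_assign_gene <- function(chrom, fs, fe, genes) {
  best <- NA_character_; best_score <- -Inf; best_ov <- -Inf
  for (g in genes) {
    if (g$chrom != chrom) next
    ov <- min(fe, g$end) - max(fs, g$start)
    if (ov <= 0) next
    score <- ov / max(g$end - g$start, fe - fs)
    better <- score > best_score ||
      (score == best_score && (ov > best_ov ||
        (ov == best_ov && g$gene_id < best)))
    if (better) { best <- g$gene_id; best_score <- score; best_ov <- ov }
  }
  best
}

## Random structured CIGAR: M runs interleaved with N/D/I, optional soft
## clips at the ends.
random_cigar <- function() {
  k <- sample(1:4, 1)
  ops <- character(0); lens <- integer(0)
  for (i in seq_len(k)) {
    ops <- c(ops, "M"); lens <- c(lens, sample(1:150, 1))
    if (i < k) {
      ops <- c(ops, sample(c("N", "D", "I"), 1))
      lens <- c(lens, sample(1:120, 1))
    }
  }
  if (runif(1) < 0.3) { ops <- c("S", ops); lens <- c(sample(1:40, 1), lens) }
  if (runif(1) < 0.3) { ops <- c(ops, "S"); lens <- c(lens, sample(1:40, 1)) }
  paste0(lens, ops, collapse = "")
}
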