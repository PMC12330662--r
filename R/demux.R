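#' Locate the poly-T tract of an oligo-dT read
#'
#' Finds the longest window that is at least `frac` thymine and at least
#' `min_run` bases long, searching the read and its reverse complement; the
#' winning window is trimmed to begin and end on a T. The poly-T tract is
#' the primary anchor for barcode assignment: the sample barcode sits
#' immediately 5' of it in the forward read layout.
#'
#' @param read A nucleotide string.
#' @param min_run Minimum tract length (default 10).
#' @param frac Minimum T fraction within the window (default 0.9).
#' @return `NULL` when no tract is found, otherwise a list with `start`,
#'   `end` (1-based, inclusive, on the strand in which the tract was found),
#'   `length` and `orientation` (`"forward"` if found on the read as given,
#'   `"reverse"` if on its reverse complement; ties go to the longer hit,
#'   then forward).
#' @export
#' @examples
#' find_polyt(paste0("AAAA", strrep("T", 12), "CCGG"))
find_polyt <- function(read, min_run = 10L, frac = 0.9) {
  stopifnot(nchar(read) > 0)
  fw <- .polyt_window_cpp(read, as.integer(min_run), frac)
  rv <- .polyt_window_cpp(revcomp(read), as.integer(min_run), frac)
  if (fw$length == 0 && rv$length == 0) return(NULL)
  if (rv$length > fw$length)
    list(start = rv$start, end = rv$end, length = rv$length,
         orientation = "reverse")
  else
    list(start = fw$start, end = fw$end, length = fw$length,
         orientation = "forward")
}

#' Locate the common primer in a read
#'
#' Best infix (semi-global) edit-distance alignment of the common-primer
#' sequence against the read and its reverse complement. The locus is
#' reported only when the distance is within `max_dist`.
#'
#' @param read A nucleotide string.
#' @param cp Common-primer sequence (at least 10 nt).
#' @param max_dist Maximum edit distance (default 3).
#' @return `NULL` if no locus within `max_dist`, otherwise a list with
#'   `start`, `end` (1-based inclusive on the strand of the hit),
#'   `distance`, and `orientation` (`"forward"`/`"reverse"`; ties go
#'   forward).
#' @export
#' @examples
#' find_common_primer(paste0("AAAA", "ACGTACGTACGTACG", "TTTT"),
#'                    "ACGTACGTACGTACG")
find_common_primer <- function(read, cp, max_dist = 3L) {
  if (nchar(cp) < 10L) stop("common primer must be at least 10 nt long")
  fw <- .edit_locate_cpp(cp, read)
  rv <- .edit_locate_cpp(cp, revcomp(read))
  best <- if (rv$distance < fw$distance)
    c(rv, orientation = "reverse") else c(fw, orientation = "forward")
  if (best$distance > max_dist) return(NULL)
  list(start = best$start, end = best$end, distance = best$distance,
       orientation = best$orientation)
}

## Orientation of a read implied by where the reverse-complemented CP is
## found (in the forward layout the read ends with revcomp(CP)). NULL when
## the CP is not found within tolerance, NA when both orientations tie.
.cp_orientation <- function(read, cp, max_dist) {
  crc <- revcomp(cp)
  fw <- .edit_locate_cpp(crc, read)
  rv <- .edit_locate_cpp(crc, revcomp(read))
  if (min(fw$distance, rv$distance) > max_dist) return(NULL)
  if (fw$distance == rv$distance) return(list(orientation = NA))
  if (fw$distance < rv$distance)
    list(orientation = "forward", start = fw$start, end = fw$end,
         distance = fw$distance)
  else
    list(orientation = "reverse", start = rv$start, end = rv$end,
         distance = rv$distance)
}

#' Assign a read to a sample barcode
#'
#' Anchored, mismatch-tolerant barcode search. The read is first oriented
#' using its poly-T tract and/or common primer (CP): the two anchors must
#' agree, otherwise no assignment is made. A window of barcode length plus
#' `window_slack` bases immediately 5' of the poly-T tract (or, when no
#' poly-T is found, at the start of the CP-oriented read) is then scanned
#' for every barcode by infix edit distance. A read is `assigned` only when
#' exactly one barcode lies within `max_dist` edits; zero matches give
#' `none_found`, two or more give `multiple_found`, and non-assigned reads
#' are excluded downstream.
#'
#' @param read A nucleotide string.
#' @param barcodes Named character vector of barcode sequences.
#' @param cp Optional common-primer sequence used as a secondary anchor.
#' @param max_dist Maximum barcode (and CP) edit distance, default 3.
#' @param min_polyt,polyt_frac Poly-T detection parameters, see
#'   [find_polyt()].
#' @param window_slack Extra bases added to the barcode search window.
#' @return A list of class `barcode_assignment`: `status` (one of
#'   `"assigned"`, `"none_found"`, `"multiple_found"`), `barcode_id`,
#'   `distance`, `orientation`, and the anchor loci (`barcode_locus`,
#'   `polyt_locus`, `cp_locus`, all on the oriented read) used by
#'   [trim_read()].
#' @export
assign_barcode <- function(read, barcodes, cp = NULL, max_dist = 3L,
                           min_polyt = 10L, polyt_frac = 0.9,
                           window_slack = 8L) {
  if (length(barcodes) == 0 || anyDuplicated(barcodes))
    stop("barcodes must be non-empty and pairwise distinct")
  if (is.null(names(barcodes)))
    names(barcodes) <- sprintf("BC%02d", seq_along(barcodes))
  none <- function() structure(list(
    status = "none_found", barcode_id = NA_character_,
    distance = NA_integer_, orientation = NA_character_,
    barcode_locus = NULL, polyt_locus = NULL, cp_locus = NULL),
    class = "barcode_assignment")

  pt <- find_polyt(read, min_run = min_polyt, frac = polyt_frac)
  cpo <- if (!is.null(cp)) .cp_orientation(read, cp, max_dist) else NULL
  if (!is.null(cpo) && is.na(cpo$orientation)) cpo <- NULL

  ## orientation from anchor geometry; conflicting anchors disqualify
  if (!is.null(pt) && !is.null(cpo) && pt$orientation != cpo$orientation)
    return(none())
  orient <- if (!is.null(pt)) pt$orientation
            else if (!is.null(cpo)) cpo$orientation
            else return(none())

  s <- if (orient == "forward") read else revcomp(read)
  cp_locus <- NULL
  if (!is.null(cp)) {
    hit <- .edit_locate_cpp(revcomp(cp), s)
    if (hit$distance <= max_dist)
      cp_locus <- list(start = hit$start, end = hit$end,
                       distance = hit$distance)
  }

  bcl <- max(nchar(barcodes))
  if (!is.null(pt)) {
    ## overlap into the tract: the detected poly-T window can swallow a
    ## T-rich barcode tail, and the infix match is indifferent to trailing
    ## T context
    win_end <- min(nchar(s), pt$start + window_slack)
    win_start <- max(1L, pt$start - (bcl + window_slack))
  } else {
    win_start <- 1L
    win_end <- min(nchar(s), bcl + window_slack)
  }
  if (win_end < win_start) return(none())
  window <- substr(s, win_start, win_end)

  hits <- lapply(barcodes, function(b) .edit_locate_cpp(b, window))
  d <- vapply(hits, `[[`, 0L, "distance")
  ok <- which(d <= max_dist)
  if (length(ok) == 0) return(none())
  if (length(ok) > 1)
    return(structure(list(
      status = "multiple_found", barcode_id = NA_character_,
      distance = unname(min(d[ok])), orientation = orient,
      barcode_locus = NULL,
      polyt_locus = pt[c("start", "end")], cp_locus = cp_locus),
      class = "barcode_assignment"))
  i <- ok[1]
  structure(list(
    status = "assigned", barcode_id = names(barcodes)[i],
    distance = unname(d[i]), orientation = orient,
    barcode_locus = list(start = win_start + hits[[i]]$start - 1L,
                         end = win_start + hits[[i]]$end - 1L),
    polyt_locus = if (is.null(pt)) NULL else pt[c("start", "end")],
    cp_locus = cp_locus), class = "barcode_assignment")
}

#' Trim primer structure from an assigned read
#'
#' Removes the barcode, poly-T tract and common-primer loci found by
#' [assign_barcode()] (their union, should they overlap) and returns the
#' internal cDNA in a canonical orientation: mRNA sense, i.e. the reverse
#' complement of the insert as it appears in the forward read layout.
#' Unassigned reads are returned unmodified and flagged.
#'
#' @param read The raw read.
#' @param assignment A `barcode_assignment` from [assign_barcode()].
#' @return A list with `sequence` and logical `trimmed`.
#' @export
trim_read <- function(read, assignment) {
  stopifnot(inherits(assignment, "barcode_assignment"))
  if (assignment$status != "assigned")
    return(list(sequence = read, trimmed = FALSE))
  s <- if (assignment$orientation == "forward") read else revcomp(read)
  lead_end <- max(c(assignment$barcode_locus$end,
                    assignment$polyt_locus$end, 0L))
  ins_start <- lead_end + 1L
  ins_end <- if (!is.null(assignment$cp_locus))
    assignment$cp_locus$start - 1L else nchar(s)
  if (ins_end < ins_start)
    return(list(sequence = "", trimmed = TRUE))
  list(sequence = revcomp(substr(s, ins_start, ins_end)), trimmed = TRUE)
}

#' Demultiplex a set of reads
#'
#' Runs [assign_barcode()] and [trim_read()] over a read set and returns a
#' per-read report. Every read receives exactly one status, so the counts of
#' `assigned`, `none_found` and `multiple_found` sum to the input count.
#'
#' @param reads Data.frame with `read_id` and `sequence` columns (as from
#'   [read_fastq()]), or a named character vector of sequences.
#' @inheritParams assign_barcode
#' @return Data.frame with columns `read_id`, `status`, `barcode_id`,
#'   `distance`, `orientation` and `trimmed_sequence` (empty for unassigned
#'   reads).
#' @export
demux_reads <- function(reads, barcodes, cp = NULL, max_dist = 3L,
                        min_polyt = 10L, polyt_frac = 0.9,
                        window_slack = 8L) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  n <- nrow(reads)
  status <- character(n); bc <- character(n); dist <- integer(n)
  orient <- character(n); trimmed <- character(n)
  for (i in seq_len(n)) {
    a <- assign_barcode(reads$sequence[i], barcodes, cp = cp,
                        max_dist = max_dist, min_polyt = min_polyt,
                        polyt_frac = polyt_frac,
                        window_slack = window_slack)
    status[i] <- a$status
    bc[i] <- if (is.na(a$barcode_id)) NA_character_ else a$barcode_id
    dist[i] <- if (is.null(a$distance) || is.na(a$distance))
      NA_integer_ else as.integer(a$distance)
    orient[i] <- a$orientation
    trimmed[i] <- if (a$status == "assigned")
      trim_read(reads$sequence[i], a)$sequence else ""
  }
  data.frame(read_id = reads$read_id, status = status, barcode_id = bc,
             distance = dist, orientation = orient,
             trimmed_sequence = trimmed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Demultiplex a FASTQ file into per-sample FASTQ files
#'
#' @param path Input FASTQ (optionally gzipped).
#' @param out_dir Output directory for per-sample FASTQ files and the
#'   `demux_report.tsv`.
#' @inheritParams assign_barcode
#' @return The demultiplexing report data.frame, invisibly.
#' @export
demux_fastq <- function(path, out_dir, barcodes, cp = NULL, max_dist = 3L,
                        min_polyt = 10L, polyt_frac = 0.9,
                        window_slack = 8L) {
  reads <- read_fastq(path)
  rep <- demux_reads(reads, barcodes, cp = cp, max_dist = max_dist,
                     min_polyt = min_polyt, polyt_frac = polyt_frac,
                     window_slack = window_slack)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (b in unique(stats::na.omit(rep$barcode_id))) {
    sel <- rep$status == "assigned" & !is.na(rep$barcode_id) &
      rep$barcode_id == b & nchar(rep$trimmed_sequence) > 0
    write_fastq(data.frame(read_id = rep$read_id[sel],
                           sequence = rep$trimmed_sequence[sel]),
                file.path(out_dir, paste0(b, ".fastq")))
  }
  .write_tsv(rep[, c("read_id", "status", "barcode_id", "distance",
                     "orientation")],
             file.path(out_dir, "demux_report.tsv"))
  invisible(rep)
}
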