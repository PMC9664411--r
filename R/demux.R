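# Demultiplexing by internal 8-mer barcode pairs, and the quality/length
# read filters applied before classification.

# Hamming distances between fixed-length string vector x and a single
# barcode (vectorized over x)
hamming_to <- function(x, bc) {
  bcv <- strsplit(bc, "", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  as.integer(rowSums(m != matrix(bcv, nrow(m), length(bcv), byrow = TRUE)))
}

#' Demultiplex reads by internal barcode pairs
#'
#' A read is assigned to sample *s* iff its 5' window matches *s*'s forward
#' barcode and its 3' window matches the reverse complement of *s*'s reverse
#' barcode (forward orientation), or the mirrored pattern (reverse
#' orientation), each within `max_mismatch` substitutions.  Barcodes are
#' trimmed from assigned reads; unassigned reads are reported and never
#' classified.  Barcode pairs must be pairwise distinct at Hamming distance
#' greater than `2 * max_mismatch`.
#'
#' @param reads A [read_set()].
#' @param barcode_pairs Data frame with columns `sample`, `fwd`, `rev`.
#' @param max_mismatch Maximum substitutions per barcode window (default 1;
#'   indels are not tolerated in the 8-mer windows).
#' @return List with `samples` (named list of trimmed per-sample
#'   `read_set`s), `unassigned` (a `read_set`), and `report` (a
#'   [filter_report()] data.frame).
#' @export
demultiplex <- function(reads, barcode_pairs, max_mismatch = 1L) {
  stopifnot(inherits(reads, "read_set"),
            all(c("sample", "fwd", "rev") %in% names(barcode_pairs)))
  check_barcode_distances(barcode_pairs, min_dist = max_mismatch)
  blen <- nchar(barcode_pairs$fwd[1])
  n <- nrow(reads)
  ns <- nrow(barcode_pairs)

  len <- nchar(reads$bases)
  ok_len <- len >= 2L * blen + 1L
  head_w <- substr(reads$bases, 1L, blen)
  tail_w <- substr(reads$bases, len - blen + 1L, len)

  best_sample <- rep(NA_integer_, n)
  best_orient <- rep(NA_character_, n)
  best_mm <- rep(.Machine$integer.max, n)
  tied <- rep(FALSE, n)

  for (s in seq_len(ns)) {
    fwd <- barcode_pairs$fwd[s]
    rev <- barcode_pairs$rev[s]
    # forward orientation: fwd at 5', revcomp(rev) at 3'
    mm_f <- hamming_to(head_w, fwd) + hamming_to(tail_w, revcomp(rev))
    # reverse orientation (read is the reverse complement of the molecule):
    # rev at 5', revcomp(fwd) at 3'
    mm_r <- hamming_to(head_w, rev) + hamming_to(tail_w, revcomp(fwd))
    for (o in 1:2) {
      mm <- if (o == 1L) mm_f else mm_r
      hit <- ok_len & (pmax(hamming_to(head_w, if (o == 1L) fwd else rev),
                            hamming_to(tail_w, if (o == 1L) revcomp(rev) else revcomp(fwd)))
                       <= max_mismatch)
      better <- hit & mm < best_mm
      tie <- hit & mm == best_mm & (best_sample != s | is.na(best_sample))
      tied[tie] <- TRUE
      tied[better] <- FALSE
      best_sample[better] <- s
      best_orient[better] <- if (o == 1L) "forward" else "reverse"
      best_mm[better] <- mm[better]
    }
  }
  assigned <- !is.na(best_sample) & !tied

  samples <- vector("list", ns)
  names(samples) <- barcode_pairs$sample
  for (s in seq_len(ns)) {
    idx <- which(assigned & best_sample == s)
    trimmed <- substr(reads$bases[idx], blen + 1L, len[idx] - blen)
    trimmedq <- substr(reads$qual[idx], blen + 1L, len[idx] - blen)
    samples[[s]] <- read_set(reads$id[idx], trimmed, trimmedq,
                             sample = barcode_pairs$sample[s],
                             orientation = best_orient[idx])
  }
  un <- which(!assigned)
  unassigned <- read_set(reads$id[un], reads$bases[un], reads$qual[un])

  report <- data.frame(
    sample = c(barcode_pairs$sample, "(unassigned)"),
    input = c(rep(NA_integer_, ns), n),
    demuxed = c(vapply(samples, nrow, integer(1)), NA_integer_),
    failed_barcode = c(rep(NA_integer_, ns), length(un)),
    stringsAsFactors = FALSE)

  list(samples = samples, unassigned = unassigned, report = report)
}

#' Quality and length filtering of reads
#'
#' Retains reads whose mean quality is at least `min_mean_q` (computed on
#' the error-probability scale: \eqn{Q = -10\log_{10}} of the mean per-base
#' error probability -- see [mean_quality()]) and whose length after
#' barcode/primer trimming is at least `min_len`.  Both boundaries are
#' inclusive.  Deterministic and idempotent.
#'
#' @param reads A [read_set()] (typically one demultiplexed sample).
#' @param min_mean_q Minimum mean read quality in Phred units (default 20).
#' @param min_len Minimum read length in bases (default 400).
#' @param maq_method Mean-quality semantics: `"prob"` (default) or
#'   `"phred"` (arithmetic mean of scores).
#' @return List with `passed` (a `read_set`) and `report` (a
#'   [filter_report()] data.frame).
#' @export
quality_length_filter <- function(reads, min_mean_q = 20, min_len = 400L,
                                  maq_method = c("prob", "phred")) {
  stopifnot(inherits(reads, "read_set"))
  maq_method <- match.arg(maq_method)
  len <- nchar(reads$bases)
  mq <- vapply(qual_ints(reads), mean_quality, numeric(1), method = maq_method)
  fail_len <- len < min_len
  fail_q <- !fail_len & mq < min_mean_q   # each read counted in one bucket
  pass <- !fail_len & !fail_q
  report <- data.frame(
    sample = if (all(is.na(reads$sample))) "(all)" else
      paste(unique(reads$sample), collapse = ","),
    demuxed = nrow(reads),
    failed_length = sum(fail_len),
    failed_maq = sum(fail_q),
    passed = sum(pass),
    stringsAsFactors = FALSE)
  list(passed = reads[pass, , drop = FALSE], report = report)
}

#' Combined per-sample filter report
#'
#' Merges a [demultiplex()] report with per-sample [quality_length_filter()]
#' reports into the standard accounting table: for the pool,
#' `input = demuxed + failed_barcode`; per sample,
#' `demuxed = passed + failed_maq + failed_length`.
#'
#' @param demux_result A [demultiplex()] result.
#' @param min_mean_q,min_len,maq_method Passed to [quality_length_filter()].
#' @return List with `samples` (named list of filtered `read_set`s) and
#'   `report` (data.frame).
#' @export
demux_filter <- function(demux_result, min_mean_q = 20, min_len = 400L,
                         maq_method = "prob") {
  out <- lapply(demux_result$samples, quality_length_filter,
                min_mean_q = min_mean_q, min_len = min_len,
                maq_method = maq_method)
  rep_rows <- do.call(rbind, lapply(out, `[[`, "report"))
  rep_rows$failed_barcode <- NA_integer_
  pool <- data.frame(sample = "(pool)",
                     demuxed = sum(rep_rows$demuxed),
                     failed_length = NA_integer_, failed_maq = NA_integer_,
                     passed = NA_integer_,
                     failed_barcode = nrow(demux_result$unassigned),
                     stringsAsFactors = FALSE)
  pool$input <- pool$demuxed + pool$failed_barcode
  rep_rows$input <- NA_integer_
  report <- rbind(pool, rep_rows)
  rownames(report) <- NULL
  list(samples = lapply(out, `[[`, "passed"),
       report = report[, c("sample", "input", "demuxed", "failed_barcode",
                           "failed_maq", "failed_length", "passed")])
}

#' @rdname demux_filter
#' @export
filter_report <- function(demux_result, ...) demux_filter(demux_result, ...)$report
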