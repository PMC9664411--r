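# Per-category amplicon-size QC and report writing.

# mode of read lengths on 10-bp-binned values (bin midpoint reported),
# stabilizing the mode against small indel jitter
binned_mode <- function(len, bin = 10L) {
  if (!length(len)) return(NA_real_)
  b <- floor(len / bin)
  tb <- table(b)
  best <- as.integer(names(tb)[which.max(tb)])
  best * bin + bin / 2
}

#' Per-category amplicon-size summaries
#'
#' Summarizes the read-length distribution of each classification bin and
#' compares it with the expectation from the locus model: unedited, indel
#' and inversion bins are expected near the reference length, the
#' productive-excision bin near the deletion-product length, and the AAV
#' integration bin is expected to shift toward larger amplicons (flagged,
#' not given a point expectation).
#'
#' @param calls Per-read calls from [classify_library()] (`calls` element).
#' @param locus A [locus_model()].
#' @param bin Histogram bin width in bp for the mode (default 10).
#' @return A `size_summary` data.frame: `category`, `n`, `min`, `median`,
#'   `max`, `mode` (binned), `expected`, `mode_deviation`.
#' @export
size_distributions <- function(calls, locus, bin = 10L) {
  stopifnot(inherits(locus, "locus_model"))
  prods <- expected_products(locus)
  ref_len <- nchar(locus$reference)
  expected <- c(unedited = ref_len, indel5 = ref_len, indel3 = ref_len,
                indel_both = ref_len, delta_exon = nchar(prods$deletion),
                inversion = ref_len, aav_integration = NA_real_,
                unclassified = NA_real_)
  rows <- lapply(outcome_categories(), function(cc) {
    len <- calls$read_length[calls$category == cc]
    if (!length(len)) {
      return(data.frame(category = cc, n = 0L, min = NA_integer_,
                        median = NA_real_, max = NA_integer_,
                        mode = NA_real_, expected = expected[[cc]],
                        mode_deviation = NA_real_, stringsAsFactors = FALSE))
    }
    m <- binned_mode(len, bin)
    data.frame(category = cc, n = length(len), min = min(len),
               median = median(len), max = max(len), mode = m,
               expected = expected[[cc]],
               mode_deviation = m - expected[[cc]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("size_summary", "data.frame")
  out
}

# per-category length histograms, counts per `bin`-bp bin
length_histograms <- function(calls, bin = 10L) {
  rows <- lapply(outcome_categories(), function(cc) {
    len <- calls$read_length[calls$category == cc]
    if (!length(len)) return(NULL)
    b <- floor(len / bin) * bin
    tb <- table(b)
    data.frame(category = cc, bin_start = as.integer(names(tb)),
               bin_end = as.integer(names(tb)) + bin - 1L,
               count = as.integer(tb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0))
  rownames(out) <- NULL
  out
}

#' Write the classification report files
#'
#' Writes, with deterministic ordering:
#' `<prefix>_category_table.tsv` and `.json` (per-category counts and
#' percentages), `<prefix>_size_summary.tsv` (per-category length
#' statistics), and `<prefix>_length_histograms.tsv` (counts per `bin`-bp
#' length bin per category).  Percentages in the TSV/JSON are formatted to
#' 2 decimals, or 4 decimals below 0.01%.
#'
#' @param result A [classify_library()] result.
#' @param locus A [locus_model()].
#' @param out_prefix Output path prefix.
#' @param bin Histogram bin width (default 10 bp).
#' @param per_read Also write `<prefix>_per_read.tsv` with one row per read.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, locus, out_prefix, bin = 10L,
                         per_read = FALSE) {
  calls <- result$calls
  tab <- result$table
  paths <- character(0)

  p <- paste0(out_prefix, "_category_table.tsv")
  out_tab <- as.data.frame(tab)
  out_tab$percent <- format_percent(out_tab$percent)
  write.table(out_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- paste0(out_prefix, "_category_table.json")
  jsonlite::write_json(
    list(sample = tab$sample[1], total = attr(tab, "total"),
         categories = setNames(as.list(tab$count), tab$category),
         percent = setNames(as.list(round(tab$percent, 4)), tab$category)),
    p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)

  sizes <- size_distributions(calls, locus, bin)
  p <- paste0(out_prefix, "_size_summary.tsv")
  write.table(as.data.frame(sizes), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)

  p <- paste0(out_prefix, "_length_histograms.tsv")
  write.table(length_histograms(calls, bin), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)

  if (per_read) {
    p <- paste0(out_prefix, "_per_read.tsv")
    write.table(calls[order(calls$id), ], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
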