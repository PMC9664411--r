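#' Construct a read set
#'
#' A `read_set` is a data.frame-backed container for sequencing reads:
#' columns `id`, `bases` (DNA string) and `qual` (Phred+33 quality string of
#' equal length), plus optional `sample` and `orientation` columns filled in
#' by demultiplexing.
#'
#' @param id Character vector of read identifiers.
#' @param bases Character vector of read sequences.
#' @param qual Character vector of Phred+33 quality strings.
#' @param sample Optional per-read sample labels.
#' @param orientation Optional per-read orientation
#'   (`"forward"`/`"reverse"`/`"unknown"`).
#' @return A `read_set` (also a data.frame).
#' @export
read_set <- function(id, bases, qual,
                     sample = NA_character_, orientation = "unknown") {
  stopifnot(length(id) == length(bases), length(bases) == length(qual))
  if (any(nchar(bases) != nchar(qual)))
    stop("bases and qualities must have equal length per read")
  df <- data.frame(id = as.character(id), bases = as.character(bases),
                   qual = as.character(qual),
                   sample = rep_len(sample, length(id)),
                   orientation = rep_len(orientation, length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads; lengths %s\n", nrow(x),
              if (nrow(x)) paste0(min(nchar(x$bases)), "-", max(nchar(x$bases)))
              else "-"))
  if (nrow(x)) print(utils::head(as.data.frame(
    x[, c("id", "sample", "orientation")], stringsAsFactors = FALSE)))
  invisible(x)
}

#' Read / write FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings FASTQ support, converting to and from
#' [read_set()].
#'
#' @param path FASTQ file path.
#' @param reads A `read_set`.
#' @return `read_fastq()` returns a `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  read_set(id = sub("\\s.*$", "", names(x)),
           bases = as.character(x),
           qual = as.character(q))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# integer Phred scores per read (list)
qual_ints <- function(reads) {
  lapply(reads$qual, phred_to_int)
}
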