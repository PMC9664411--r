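#' @useDynLib dualguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rgeom rnorm runif setNames coef lm predict aggregate residuals
#' @importFrom utils write.table read.table head adist
NULL

#' The fixed editing-outcome category vocabulary
#'
#' Category labels used throughout the package, in reporting order:
#' `unedited`, `indel5`, `indel3`, `indel_both`, `delta_exon`, `inversion`,
#' `aav_integration`, `unclassified`.  `unclassified` never occurs as a
#' simulated truth label.
#'
#' @return Character vector of the eight category names.
#' @export
outcome_categories <- function() {
  c("unedited", "indel5", "indel3", "indel_both", "delta_exon",
    "inversion", "aav_integration", "unclassified")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (ACGTN, case preserved as upper).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) rawToChar(rev(charToRaw(s))),
         character(1), USE.NAMES = FALSE)
}

# single uppercase ACGT-only DNA string
assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop(what, " must be a single non-empty DNA string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters other than A/C/G/T (ambiguity codes are rejected)",
         call. = FALSE)
  invisible(x)
}

# seeded uniform random DNA, used by the simulator and test fixtures
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Phred quality conversions (Sanger, Phred+33)
#'
#' `phred_to_int()` decodes an ASCII quality string to integer Phred scores;
#' `int_to_phred()` encodes integer scores (0-93) to ASCII.
#'
#' @param qual A quality string (Phred+33).
#' @param q Integer vector of Phred scores.
#' @return Integer vector, or single quality string.
#' @export
phred_to_int <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' @rdname phred_to_int
#' @export
int_to_phred <- function(q) {
  q <- as.integer(round(q))
  if (any(q < 0L | q > 93L)) stop("Phred scores must lie in [0, 93]")
  intToUtf8(q + 33L)
}

#' Mean read quality on the error-probability scale
#'
#' The mean quality of a read is computed as
#' \eqn{Q = -10 \log_{10}(\overline{p})} where \eqn{\overline{p}} is the
#' arithmetic mean of the per-base error probabilities
#' \eqn{p_i = 10^{-q_i/10}}.  This is the error-rate-faithful reading of a
#' minimum-average-quality (maq) filter; the arithmetic mean of the Phred
#' scores themselves is available via `method = "phred"`.
#'
#' @param q Integer vector of per-base Phred scores.
#' @param method `"prob"` (default, probability-scale mean) or `"phred"`
#'   (arithmetic mean of scores).
#' @return Mean quality in Phred units.
#' @export
#' @examples
#' mean_quality(c(rep(30, 5), rep(10, 5)))  # ~ 12.97, not 20
mean_quality <- function(q, method = c("prob", "phred")) {
  method <- match.arg(method)
  if (length(q) == 0L) return(NA_real_)
  if (method == "phred") return(mean(q))
  -10 * log10(mean(10^(-q / 10)))
}

# evenly spaced integer offsets in [-span, span], n of them, deduplicated
stagger_shifts <- function(n, span) {
  if (n <= 1L || span <= 0L) return(0L)
  sort(unique(as.integer(round(seq(-span, span, length.out = n)))))
}
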