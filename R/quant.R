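# qPCR quantification arithmetic: standard curves, absolute copies,
# percent exon-skipped transcripts, vector genomes per host genome, and
# Pfaffl efficiency-corrected expression ratios.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Cq = m * log10(copies) + b` to a serial dilution
#' series.  The amplification factor is `A = 10^(-1/m)` (2.0 for perfect
#' doubling, i.e. slope -3.3219) and the efficiency `E = A - 1`.
#'
#' @param copies Template copy numbers (> 0), at least 3 distinct dilutions.
#' @param cq Measured quantification cycles, same length.
#' @return A `standard_curve` object with components `slope`, `intercept`,
#'   `r_squared`, `amplification`, `efficiency` (fraction), and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' sc <- fit_standard_curve(10^(3:7), -3.3219 * (3:7) + 38)
#' sc$amplification  # 2.0
#' copies_from_cq(sc, 28)  # 1000
fit_standard_curve <- function(copies, cq) {
  if (length(copies) != length(cq)) stop("copies and cq must have equal length")
  if (length(copies) < 3L) stop("a standard curve needs at least 3 dilution points")
  if (any(copies <= 0)) stop("copies must be positive")
  fit <- lm(cq ~ log10(copies))
  m <- unname(coef(fit)[2L]); b <- unname(coef(fit)[1L])
  if (!is.finite(m) || m >= 0) stop("invalid curve: slope must be negative")
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = m, intercept = b, r_squared = r2,
                 amplification = 10^(-1 / m),
                 efficiency = 10^(-1 / m) - 1,
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.4f * log10(copies) + %.4f | r^2 = %.4f | E = %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Absolute copy number from a Cq value
#'
#' Inverts the standard curve: `copies = 10^((Cq - b) / m)`.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param cq Cq value(s).
#' @return Copy number(s).
#' @export
copies_from_cq <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Percentage of exon-skipped transcripts
#'
#' The fraction of exon-deleted transcripts relative to the total
#' (full-length + exon-deleted), as a percentage.
#'
#' @param copies_dex Copy number of the exon-deleted (skipped) transcript.
#' @param copies_fl Copy number of the full-length transcript.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' percent_skipped(12, 88)  # 12
percent_skipped <- function(copies_dex, copies_fl) {
  if (any(copies_dex < 0) || any(copies_fl < 0)) stop("copies must be >= 0")
  tot <- copies_dex + copies_fl
  if (any(tot == 0)) stop("undefined: both copy numbers are zero")
  100 * copies_dex / tot
}

#' Vector genomes per host genome
#'
#' @param vg_copies AAV vector genome copies (e.g. from a transgene assay).
#' @param genome_copies Host genome copies (e.g. from a single-copy gene
#'   assay).
#' @param ploidy If > 1, `genome_copies` is interpreted as single-copy-gene
#'   (allele) copies and divided by `ploidy` to obtain genome equivalents;
#'   default 1 (no adjustment).
#' @return vg per host genome.
#' @export
vg_per_genome <- function(vg_copies, genome_copies, ploidy = 1) {
  if (any(genome_copies <= 0)) stop("genome_copies must be > 0")
  if (any(vg_copies < 0)) stop("vg_copies must be >= 0")
  vg_copies / (genome_copies / ploidy)
}

#' Genome copies from a gDNA mass
#'
#' Converts a genomic-DNA standard mass to diploid genome equivalents using
#' the conventional 6.6 pg per diploid mammalian genome.
#'
#' @param mass_pg gDNA mass in picograms.
#' @param pg_per_genome Mass of one diploid genome in pg (default 6.6).
#' @return Genome copy number.
#' @export
mass_to_genome_copies <- function(mass_pg, pg_per_genome = 6.6) {
  if (any(mass_pg < 0)) stop("mass must be >= 0")
  mass_pg / pg_per_genome
}

#' Pfaffl efficiency-corrected expression ratio
#'
#' `ratio = E_target^dCq_target / E_ref^dCq_ref`, where efficiencies are
#' amplification factors (2 = perfect doubling) and each dCq is
#' `Cq_control - Cq_sample` (so a ratio > 1 means up in the sample).
#'
#' @param e_target,e_ref Amplification factors in (1, 2.2].
#' @param dcq_target,dcq_ref Cq differences (control minus sample).
#' @return The expression ratio.
#' @export
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)  # 2
pfaffl_ratio <- function(e_target, dcq_target, e_ref, dcq_ref) {
  if (any(e_target <= 1) || any(e_ref <= 1))
    stop("efficiencies must be amplification factors > 1")
  if (any(e_target > 2.2) || any(e_ref > 2.2))
    stop("amplification factors above 2.2 are not physical")
  (e_target^dcq_target) / (e_ref^dcq_ref)
}

#' Read a Cq table and combine technical replicates
#'
#' Reads a TSV with columns `sample`, `assay`, `cq` (and optionally
#' `replicate`), averaging technical replicates by mean Cq.
#'
#' @param path TSV path.
#' @return data.frame with one row per (sample, assay): `sample`, `assay`,
#'   `cq` (mean), `n_reps`.
#' @export
read_cq_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "cq")
  if (!all(need %in% names(df)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  agg <- aggregate(cq ~ sample + assay, data = df, FUN = mean)
  n <- aggregate(cq ~ sample + assay, data = df, FUN = length)
  agg$n_reps <- n$cq
  agg[order(agg$sample, agg$assay), ]
}

#' Absolute quantification of a sample set
#'
#' Converts mean Cq values to absolute copies via per-assay standard
#' curves and derives percent exon-skipped transcripts and/or vector
#' genomes per host genome where the relevant assays are present.
#'
#' @param cq_means Output of [read_cq_table()] (or a data.frame with
#'   `sample`, `assay`, `cq`).
#' @param curves Named list of [fit_standard_curve()] objects, one per
#'   assay name appearing in `cq_means`.
#' @param fl_assay,dex_assay Assay names for the full-length and
#'   exon-deleted transcript targets (set to NULL to skip).
#' @param vg_assay,genome_assay Assay names for vector genome and host
#'   genome targets (set to NULL to skip).
#' @param ploidy Passed to [vg_per_genome()].
#' @return data.frame with one row per sample: absolute copies per assay,
#'   and `percent_dex` / `vg_per_genome` columns where computable.
#' @export
quantify_samples <- function(cq_means, curves,
                             fl_assay = "fl", dex_assay = "dex",
                             vg_assay = NULL, genome_assay = NULL,
                             ploidy = 1) {
  missing_curves <- setdiff(unique(cq_means$assay), names(curves))
  if (length(missing_curves))
    stop("no standard curve for assay: ", paste(missing_curves, collapse = ", "))
  cq_means$copies <- mapply(function(a, q) copies_from_cq(curves[[a]], q),
                            cq_means$assay, cq_means$cq)
  samples <- unique(cq_means$sample)
  get_copies <- function(s, a) {
    v <- cq_means$copies[cq_means$sample == s & cq_means$assay == a]
    if (length(v)) v[1] else NA_real_
  }
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (a in unique(cq_means$assay))
    out[[paste0("copies_", a)]] <- vapply(samples, get_copies, numeric(1), a = a)
  if (!is.null(fl_assay) && !is.null(dex_assay) &&
      all(c(fl_assay, dex_assay) %in% cq_means$assay)) {
    out$percent_dex <- percent_skipped(out[[paste0("copies_", dex_assay)]],
                                       out[[paste0("copies_", fl_assay)]])
  }
  if (!is.null(vg_assay) && !is.null(genome_assay) &&
      all(c(vg_assay, genome_assay) %in% cq_means$assay)) {
    out$vg_per_genome <- vg_per_genome(out[[paste0("copies_", vg_assay)]],
                                       out[[paste0("copies_", genome_assay)]],
                                       ploidy = ploidy)
  }
  out
}
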