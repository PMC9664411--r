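#' Locate an SaCas9 guide site on an amplicon reference
#'
#' Searches both strands of `reference` for a unique occurrence of
#' `protospacer` followed (on the protospacer strand) by a valid SaCas9 PAM
#' matching `NNGRRT` (R = A or G).  The blunt double-strand break is placed
#' 3 nt 5' of the PAM, the standard Cas9 cleavage offset; the position is
#' reported as an inter-base coordinate on the plus strand of the reference
#' (0 = before the first base), so it is strand-invariant.
#'
#' @param reference Amplicon reference sequence (plus strand, ACGT).
#' @param protospacer Guide protospacer sequence, typically 20-21 nt.
#' @param name Optional label for the guide.
#' @param cut_offset Distance of the blunt cut from the PAM-proximal end of
#'   the protospacer, in nt (default 3).
#' @return A `guide_site` object: list with `name`, `protospacer`, `pam`,
#'   `strand` (`"+"`/`"-"`), `match_start` (1-based start of the protospacer
#'   match on the reference), and `cut_pos` (inter-base cut coordinate).
#' @export
#' @examples
#' ref <- paste0(strrep("A", 20), "GGTTCACTGACTCGATCAGGT", "TTGAAT", strrep("C", 20))
#' find_guide_site(ref, "GGTTCACTGACTCGATCAGGT")
find_guide_site <- function(reference, protospacer, name = "guide",
                            cut_offset = 3L) {
  assert_dna(reference, "reference")
  assert_dna(protospacer, "protospacer")
  plen <- nchar(protospacer)
  rlen <- nchar(reference)
  if (plen + 6L > rlen) stop("guide not found")

  hits <- list()
  occ_any <- FALSE

  # plus strand: protospacer at [s, s+plen), PAM immediately 3'
  for (s in find_all(reference, protospacer)) {
    occ_any <- TRUE
    pam_start <- s + plen
    if (pam_start + 5L > rlen) next
    pam <- substr(reference, pam_start, pam_start + 5L)
    if (is_nngrrt(pam)) {
      hits[[length(hits) + 1L]] <- list(
        strand = "+", match_start = s, pam = pam,
        cut_pos = (pam_start - 1L) - cut_offset  # inter-base: PAM 0-based start - offset
      )
    }
  }
  # minus strand: revcomp(protospacer) at [s, s+plen); PAM (revcomp'd) just 5'
  for (s in find_all(reference, revcomp(protospacer))) {
    occ_any <- TRUE
    if (s - 6L < 1L) next
    pam <- revcomp(substr(reference, s - 6L, s - 1L))
    if (is_nngrrt(pam)) {
      hits[[length(hits) + 1L]] <- list(
        strand = "-", match_start = s, pam = pam,
        cut_pos = (s - 1L) + cut_offset
      )
    }
  }

  if (length(hits) == 0L) {
    if (occ_any) stop("invalid PAM") else stop("guide not found")
  }
  if (length(hits) > 1L) stop("ambiguous guide")
  h <- hits[[1L]]
  structure(
    list(name = name, protospacer = protospacer, pam = h$pam,
         strand = h$strand, match_start = h$match_start,
         cut_pos = as.integer(h$cut_pos)),
    class = "guide_site"
  )
}

# all 1-based start positions of fixed pattern in subject (overlapping)
find_all <- function(subject, pattern) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (i < 0L) break
    out <- c(out, from + as.integer(i) - 1L)
    from <- from + as.integer(i)
  }
  out
}

is_nngrrt <- function(pam) {
  nchar(pam) == 6L && grepl("^..G[AG][AG]T$", pam)
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("<guide_site> %s: %s | PAM %s | strand %s | cut at %d\n",
              x$name, x$protospacer, x$pam, x$strand, x$cut_pos))
  invisible(x)
}

#' Build a locus model for a dual-guide exon-excision amplicon
#'
#' A `locus_model` ties together the unedited amplicon reference
#' (primer-to-primer), the target exon, the two flanking guide sites, the
#' barcoded primer definitions, and the AAV vector backbone sequences against
#' which integration is detected.
#'
#' @param reference Unedited amplicon sequence (plus strand, ACGT only;
#'   ambiguity codes are rejected).
#' @param exon Integer length-2 vector, 1-based inclusive interval of the
#'   target exon on the reference.
#' @param guide5,guide3 `guide_site` objects (or protospacer strings, located
#'   with [find_guide_site()]); `guide5` must cut 5' of `guide3`, and the exon
#'   must lie strictly between the two cuts.
#' @param aav_backbones Named character vector of AAV vector backbone
#'   sequences (may be empty).
#' @param fwd_primer,rev_primer Optional primer sequences (informational; the
#'   reference is primer-to-primer).
#' @return A `locus_model` object.
#' @seealso [expected_products()], [derive_features()], [read_locus_config()]
#' @export
locus_model <- function(reference, exon, guide5, guide3,
                        aav_backbones = character(0),
                        fwd_primer = NULL, rev_primer = NULL) {
  assert_dna(reference, "reference")
  if (is.character(guide5)) guide5 <- find_guide_site(reference, guide5, "guide5")
  if (is.character(guide3)) guide3 <- find_guide_site(reference, guide3, "guide3")
  stopifnot(inherits(guide5, "guide_site"), inherits(guide3, "guide_site"))
  exon <- as.integer(exon)
  if (length(exon) != 2L || exon[1] > exon[2] || exon[1] < 1L ||
      exon[2] > nchar(reference))
    stop("exon must be a valid 1-based interval on the reference")
  cut5 <- guide5$cut_pos
  cut3 <- guide3$cut_pos
  if (cut5 >= cut3) stop("guide order violation")
  # exon strictly between the cuts (cut positions are inter-base)
  if (exon[1] <= cut5 || exon[2] > cut3)
    stop("exon must lie strictly between the two cut sites")
  if (length(aav_backbones)) {
    if (is.null(names(aav_backbones)) || any(names(aav_backbones) == ""))
      stop("aav_backbones must be named")
    for (i in seq_along(aav_backbones))
      assert_dna(aav_backbones[[i]], paste0("AAV backbone '", names(aav_backbones)[i], "'"))
  }
  structure(
    list(reference = reference, exon = exon,
         guide5 = guide5, guide3 = guide3,
         aav_backbones = aav_backbones,
         fwd_primer = fwd_primer, rev_primer = rev_primer),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %d bp amplicon; exon [%d, %d] (%d bp)\n",
              nchar(x$reference), x$exon[1], x$exon[2],
              x$exon[2] - x$exon[1] + 1L))
  cat(sprintf("  5' cut at %d (%s), 3' cut at %d (%s); inter-cut %d bp\n",
              x$guide5$cut_pos, x$guide5$strand,
              x$guide3$cut_pos, x$guide3$strand,
              x$guide3$cut_pos - x$guide5$cut_pos))
  p <- expected_products(x)
  cat(sprintf("  expected deletion product %d bp; inversion product %d bp\n",
              nchar(p$deletion), nchar(p$inversion)))
  if (length(x$aav_backbones))
    cat(sprintf("  AAV backbones: %s\n",
                paste(sprintf("%s (%d bp)", names(x$aav_backbones),
                              nchar(x$aav_backbones)), collapse = ", ")))
  invisible(x)
}

#' Expected edited products of a dual-guide locus
#'
#' The productive deletion product excises everything between the two cuts
#' and fuses the flanks; the inversion product re-inserts the excised
#' fragment in reverse-complement orientation, preserving total length.
#'
#' @param locus A `locus_model`.
#' @return List with DNA strings `deletion` and `inversion`.
#' @export
#' @examples
#' loc <- synthetic_locus(seed = 1)
#' nchar(expected_products(loc)$deletion)  # 446 for the 833-bp default
expected_products <- function(locus) {
  stopifnot(inherits(locus, "locus_model"))
  ref <- locus$reference
  cut5 <- locus$guide5$cut_pos
  cut3 <- locus$guide3$cut_pos
  if (cut5 >= cut3) stop("guide order violation")
  left <- substr(ref, 1L, cut5)                    # bases 1..cut5
  mid <- substr(ref, cut5 + 1L, cut3)              # excised fragment
  right <- substr(ref, cut3 + 1L, nchar(ref))
  list(deletion = paste0(left, right),
       inversion = paste0(left, revcomp(mid), right))
}

#' Read a locus definition from a YAML config
#'
#' Expected fields: `reference` (inline sequence or `reference_fasta` path),
#' `exon: [start, end]` (1-based inclusive), `guides: {guide5: <protospacer>,
#' guide3: <protospacer>}`, optional `aav_backbones` (named inline sequences
#' or `aav_fasta` path), and optional `primers: {fwd, rev}`.
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return A `locus_model`.
#' @export
read_locus_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base_dir <- if (is.character(path)) dirname(path) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)

  if (!is.null(cfg[["reference"]])) {
    reference <- toupper(cfg[["reference"]])
  } else if (!is.null(cfg[["reference_fasta"]])) {
    fa <- Biostrings::readDNAStringSet(resolve(cfg[["reference_fasta"]]))
    reference <- as.character(fa[[1L]])
  } else stop("config must provide 'reference' or 'reference_fasta'")

  aav <- character(0)
  if (!is.null(cfg[["aav_backbones"]])) {
    aav <- vapply(cfg[["aav_backbones"]], toupper, character(1))
  } else if (!is.null(cfg[["aav_fasta"]])) {
    fa <- Biostrings::readDNAStringSet(resolve(cfg[["aav_fasta"]]))
    aav <- setNames(as.character(fa), names(fa))
  }
  guides <- cfg[["guides"]]
  if (is.null(guides[["guide5"]]) || is.null(guides[["guide3"]]))
    stop("config must provide guides$guide5 and guides$guide3 protospacers")

  locus_model(
    reference = reference,
    exon = unlist(cfg[["exon"]]),
    guide5 = find_guide_site(reference, toupper(guides[["guide5"]]), "guide5"),
    guide3 = find_guide_site(reference, toupper(guides[["guide3"]]), "guide3"),
    aav_backbones = aav,
    fwd_primer = cfg[["primers"]][["fwd"]], rev_primer = cfg[["primers"]][["rev"]]
  )
}
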