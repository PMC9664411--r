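#' Derive the diagnostic k-mer feature set for a locus
#'
#' Builds the named k-mer collections that drive read classification:
#'
#' * `intact5`, `intact3` -- k-mers spanning each unedited cut-site junction;
#' * `fusion` -- k-mers spanning the intron-intron seam of the deletion
#'   product;
#' * `inversion_left`, `inversion_right` -- k-mers spanning the two junctions
#'   of the inversion product;
#' * `exon_internal` -- k-mers internal to the target exon;
#' * `aav:<vector>:fwd` / `aav:<vector>:rev` -- every k-mer (at `aav_stride`)
#'   of each AAV backbone, in both orientations, deduplicated.
#'
#' Junction k-mers are centered on their junction, with `n_per_junction`
#' staggered copies (shifts up to +/-4, constrained so at least `floor(k/3)`
#' bases remain on both sides of the junction) to tolerate clustered
#' sequencing errors.  At build time every edited-product and AAV k-mer is
#' checked against the unedited reference: any such k-mer occurring in the
#' reference (either strand) within `max_dist` edits makes the set
#' non-diagnostic and is an error, as is the same k-mer appearing under two
#' feature names.
#'
#' @param locus A [locus_model()].
#' @param k K-mer length in bases (default 25).
#' @param n_per_junction Number of staggered k-mers per junction (default 3).
#' @param max_dist Maximum edit distance used for matching (and for the
#'   build-time diagnosticity check); default 2.
#' @param n_exon Number of exon-internal k-mers (default `n_per_junction`).
#' @param aav_stride Stride between successive AAV backbone k-mers
#'   (default 1, i.e. every contiguous k-mer).
#' @return A `feature_set` object: list with `k`, `max_dist`, and `features`
#'   (named list of character vectors of k-mers).
#' @export
derive_features <- function(locus, k = 25L, n_per_junction = 3L,
                            max_dist = 2L, n_exon = n_per_junction,
                            aav_stride = 1L) {
  stopifnot(inherits(locus, "locus_model"))
  k <- as.integer(k)
  if (k < 3L || k > 64L) stop("k must be in 3..64")
  if (max_dist < 0L || max_dist >= k) stop("max_dist must be in [0, k)")
  if (n_per_junction < 1L) stop("n_per_junction must be >= 1")
  ref <- locus$reference
  cut5 <- locus$guide5$cut_pos
  cut3 <- locus$guide3$cut_pos
  prods <- expected_products(locus)

  left_flank <- k %/% 2L                    # bases 5' of the junction
  span <- min(4L, left_flank - k %/% 3L)    # max stagger keeping floor(k/3) each side
  shifts <- stagger_shifts(n_per_junction, max(span, 0L))

  shortest_flank <- min(cut5, nchar(ref) - cut3,
                        cut3 - cut5, locus$exon[2] - locus$exon[1] + 1L)
  if (k > shortest_flank)
    stop("k exceeds the shortest flank/exon length for this locus")

  junction_kmers <- function(seq, pos) {
    # pos: inter-base junction coordinate on seq
    starts <- pos - left_flank + shifts            # 0-based k-mer starts
    starts <- starts[starts >= 0L & starts + k <= nchar(seq)]
    unique(substring(seq, starts + 1L, starts + k))
  }

  feats <- list(
    intact5 = junction_kmers(ref, cut5),
    intact3 = junction_kmers(ref, cut3),
    fusion = junction_kmers(prods$deletion, cut5),
    inversion_left = junction_kmers(prods$inversion, cut5),
    inversion_right = junction_kmers(prods$inversion, cut3)
  )

  # exon-internal k-mers, evenly spaced and fully inside the exon
  e1 <- locus$exon[1]; e2 <- locus$exon[2]
  n_exon <- max(1L, as.integer(n_exon))
  starts <- unique(as.integer(round(seq(e1, e2 - k + 1L,
                                        length.out = min(n_exon, e2 - k + 2L - e1)))))
  feats$exon_internal <- unique(substring(ref, starts, starts + k - 1L))

  for (vec in names(locus$aav_backbones)) {
    bb <- locus$aav_backbones[[vec]]
    if (nchar(bb) < k) stop("AAV backbone '", vec, "' is shorter than k")
    st <- seq.int(1L, nchar(bb) - k + 1L, by = max(1L, as.integer(aav_stride)))
    feats[[paste0("aav:", vec, ":fwd")]] <- unique(substring(bb, st, st + k - 1L))
    rb <- revcomp(bb)
    feats[[paste0("aav:", vec, ":rev")]] <- unique(substring(rb, st, st + k - 1L))
  }

  fs <- structure(
    list(k = k, max_dist = as.integer(max_dist), features = feats,
         cache = new.env(parent = emptyenv())),
    class = "feature_set"
  )
  validate_feature_set(fs, ref)
  fs
}

# build-time checks: k-mer lengths, cross-feature collisions, diagnosticity
validate_feature_set <- function(fs, reference = NULL) {
  all_kmers <- unlist(fs$features, use.names = FALSE)
  if (any(nchar(all_kmers) != fs$k))
    stop("all k-mers must have length exactly k")
  if (any(grepl("[^ACGT]", all_kmers)))
    stop("k-mers must be uppercase ACGT")
  owner <- rep(names(fs$features), lengths(fs$features))
  dup <- duplicated(all_kmers)
  if (any(dup)) {
    clash <- unique(owner[all_kmers %in% all_kmers[dup]])
    if (length(clash) > 1L)
      stop("non-diagnostic feature set: k-mer assigned to multiple features (",
           paste(clash, collapse = ", "), ")")
  }
  if (!is.null(reference)) {
    # edited-product / AAV k-mers must not occur in the unedited reference
    diag_names <- grep("^(fusion|inversion_left|inversion_right|aav:)",
                       names(fs$features), value = TRUE)
    for (nm in diag_names) {
      hits <- match_features(reference, fs, features = nm)
      if (nrow(hits) > 0L)
        stop("non-diagnostic feature set: '", nm,
             "' k-mer occurs in the unedited reference within max_dist")
    }
  }
  invisible(fs)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> k = %d, max_dist = %d\n", x$k, x$max_dist))
  n <- lengths(x$features)
  for (i in seq_along(n))
    cat(sprintf("  %-20s %d k-mer%s\n", names(n)[i], n[i],
                if (n[i] == 1L) "" else "s"))
  invisible(x)
}

#' Write / read a feature set as TSV
#'
#' Two-column TSV (`feature`, `kmer`), one row per k-mer.
#'
#' @param fs A `feature_set`.
#' @param path Output (or input) TSV path.
#' @param max_dist Matching tolerance recorded on re-load (the TSV stores only
#'   sequences).
#' @return `read_features_tsv()` returns a `feature_set`.
#' @export
write_features_tsv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- data.frame(feature = rep(names(fs$features), lengths(fs$features)),
                   kmer = unlist(fs$features, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path, max_dist = 2L) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  feats <- split(df$kmer, df$feature)
  # preserve first-appearance order
  feats <- feats[unique(df$feature)]
  k <- unique(nchar(unlist(feats, use.names = FALSE)))
  if (length(k) != 1L) stop("all k-mers must have length exactly k")
  fs <- structure(
    list(k = as.integer(k), max_dist = as.integer(max_dist), features = feats,
         cache = new.env(parent = emptyenv())),
    class = "feature_set"
  )
  validate_feature_set(fs)
  fs
}
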