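# Matching layer: thin R wrapper over the compiled seed-and-verify engine.
# A compiled matcher is built once per (feature_set, max_dist) and cached on
# the feature_set (external pointers do not survive serialization; the cache
# is rebuilt transparently).

matcher_for <- function(fs, max_dist = fs$max_dist) {
  key <- paste0("d", max_dist)
  cache <- fs$cache
  if (!is.null(cache[[key]]) && .matcher_valid(cache[[key]]$ptr)) {
    return(cache[[key]])
  }
  feats <- names(fs$features)
  kmers <- unlist(fs$features, use.names = FALSE)
  fid <- rep(seq_along(feats) - 1L, lengths(fs$features))
  # forward k-mers plus reverse complements: a feature is hit if any of its
  # k-mers occurs in the read on either strand
  tab_kmers <- c(kmers, revcomp(kmers))
  tab_fid <- c(fid, fid)
  tab_strand <- c(rep(1L, length(kmers)), rep(-1L, length(kmers)))
  ptr <- .matcher_build(tab_kmers, tab_fid, tab_strand,
                        length(feats), as.integer(max_dist))
  obj <- list(ptr = ptr, features = feats, kmers = tab_kmers)
  cache[[key]] <- obj
  obj
}

#' Match diagnostic feature k-mers in a read
#'
#' A feature is hit iff any of its k-mers occurs in the read or its reverse
#' complement at Levenshtein edit distance (substitutions + indels) at most
#' `max_dist`.  The best (lowest-distance) hit per feature is reported, ties
#' broken toward the leftmost offset; for inexact hits the reported offset is
#' accurate to within `max_dist` bases.
#'
#' @param read A DNA string, or a [read_set()] (all reads matched at once).
#' @param fs A [derive_features()] feature set.
#' @param max_dist Override of the feature set's matching tolerance.
#' @param features Optional character vector restricting which features are
#'   reported.
#' @return A data.frame of match hits with columns `read` (id or index),
#'   `feature`, `kmer`, `offset` (1-based), `strand` (`"+"`/`"-"`), `dist`.
#' @export
match_features <- function(read, fs, max_dist = fs$max_dist, features = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  hm <- match_matrix(read, fs, max_dist)
  hits_long(hm, features)
}

# core batched matching: returns list of matrices (dist/start/strand/kmer)
# with rows = reads, cols = features, plus ids and the matcher
match_matrix <- function(read, fs, max_dist = fs$max_dist) {
  if (inherits(read, "read_set")) {
    seqs <- read$bases
    ids <- read$id
  } else {
    stopifnot(is.character(read))
    seqs <- unname(read)
    ids <- if (!is.null(names(read))) names(read) else as.character(seq_along(read))
  }
  m <- matcher_for(fs, max_dist)
  res <- .matcher_match(m$ptr, seqs)
  colnames(res$dist) <- m$features
  res$ids <- ids
  res$matcher <- m
  res
}

hits_long <- function(hm, features = NULL) {
  dist <- hm$dist
  feats <- colnames(dist)
  keep_f <- if (is.null(features)) seq_along(feats) else match(features, feats)
  if (anyNA(keep_f)) stop("unknown feature name")
  out <- data.frame(read = character(0), feature = character(0),
                    kmer = character(0), offset = integer(0),
                    strand = character(0), dist = integer(0),
                    stringsAsFactors = FALSE)
  for (j in keep_f) {
    hit <- which(!is.na(dist[, j]))
    if (!length(hit)) next
    out <- rbind(out, data.frame(
      read = hm$ids[hit],
      feature = feats[j],
      kmer = hm$matcher$kmers[hm$kmer[hit, j]],
      offset = hm$start[hit, j],
      strand = ifelse(hm$strand[hit, j] > 0L, "+", "-"),
      dist = dist[hit, j],
      stringsAsFactors = FALSE
    ))
  }
  out[order(match(out$read, hm$ids), out$feature), , drop = FALSE]
}
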