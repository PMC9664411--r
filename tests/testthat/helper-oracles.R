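# Independent oracles and fixture builders shared across tests.

# uniform random DNA string
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

rc <- function(x) dualguide::revcomp(x)

# Exhaustive sliding-window Levenshtein oracle: minimum edit distance of
# `kmer` to any substring of `read` or its reverse complement, capped at
# max_dist (returns NA if no substring is within max_dist).  Enumerates every
# (start, length) window with length in [k - d, k + d] via utils::adist.
oracle_min_dist <- function(read, kmer, max_dist) {
  k <- nchar(kmer)
  best <- Inf
  for (seqs in c(read, rc(read))) {
    n <- nchar(seqs)
    for (len in max(1L, k - max_dist):(k + max_dist)) {
      if (len > n) next
      starts <- seq_len(n - len + 1L)
      subs <- substring(seqs, starts, starts + len - 1L)
      best <- min(best, min(adist(kmer, subs)))
    }
  }
  if (best <= max_dist) as.integer(best) else NA_integer_
}

# Brute-force guide-site oracle: scan every position on both strands for an
# exact protospacer occurrence with a valid NNGRRT PAM; returns inter-base
# cut positions (3 nt 5' of the PAM on the protospacer strand).
oracle_guide_scan <- function(reference, protospacer) {
  plen <- nchar(protospacer)
  rlen <- nchar(reference)
  cuts <- integer(0)
  for (s in seq_len(rlen - plen + 1L)) {
    if (substr(reference, s, s + plen - 1L) == protospacer &&
        s + plen + 5L <= rlen &&
        grepl("^..G[AG][AG]T$", substr(reference, s + plen, s + plen + 5L))) {
      cuts <- c(cuts, (s + plen - 1L) - 1L - 3L + 1L)  # 0-based PAM start - 3
    }
    if (substr(reference, s, s + plen - 1L) == rc(protospacer) &&
        s - 6L >= 1L &&
        grepl("^..G[AG][AG]T$", rc(substr(reference, s - 6L, s - 1L)))) {
      cuts <- c(cuts, (s - 1L) + 3L)
    }
  }
  cuts
}

# ad-hoc feature set over explicit k-mer lists (bypasses locus derivation)
make_fs <- function(kmers, max_dist = 2L) {
  k <- unique(nchar(unlist(kmers)))
  stopifnot(length(k) == 1L)
  structure(list(k = as.integer(k), max_dist = as.integer(max_dist),
                 features = lapply(kmers, unname),
                 cache = new.env(parent = emptyenv())),
            class = "feature_set")
}

# mutate a k-mer with exactly n substitutions at distinct positions
mutate_subs <- function(kmer, n) {
  b <- strsplit(kmer, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(b), n)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

# apply exactly n random single-base edits (sub/ins/del) to a string
mutate_edits <- function(x, n) {
  for (i in seq_len(n)) {
    b <- strsplit(x, "", fixed = TRUE)[[1]]
    op <- sample(c("sub", "ins", "del"), 1L)
    p <- sample(length(b), 1L)
    b <- switch(op,
                sub = { b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L); b },
                ins = append(b, sample(c("A", "C", "G", "T"), 1L), after = p),
                del = b[-p])
    x <- paste(b, collapse = "")
  }
  x
}

# the default 833-bp study locus, cached per test session
study_locus <- local({
  loc <- NULL
  function() {
    if (is.null(loc)) loc <<- dualguide::synthetic_locus(seed = 1)
    loc
  }
})
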