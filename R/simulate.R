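# Synthetic-library generator: a seeded, desk-scale stand-in for a CCS-style
# long-read amplicon library from a dual-guide exon-excision experiment.

# Editing-outcome proportions: midpoints of the reported per-library ranges
# (unedited 82-86%, 5' indels 9.9-13.4%, 3' indels ~2% background, indels at
# both sites ~0.5%, productive excision 0.43-0.67%, inversion 0.03-0.06%,
# AAV integration 0.38-1.11%), normalized to a proper distribution.
default_proportions <- function() {
  raw <- c(unedited = 0.84, indel5 = 0.1165, indel3 = 0.02,
           indel_both = 0.005, delta_exon = 0.0055, inversion = 0.00045,
           aav_integration = 0.00745)
  raw / sum(raw)
}

# Fixed default demultiplexing barcodes: 8-mers, pairwise Hamming distance
# >= 4 across the pooled forward + reverse sets.
default_barcode_pairs <- function(n_samples = 1L) {
  fwd <- c("AAAACTCC", "ATGTGTAA", "GTAGAATC", "TTGCACTC", "GGCCTTTC")
  rev <- c("CATATCTC", "CCCTAAAG", "TACAATTA", "ATCCCTAC", "ACTGTATA")
  if (n_samples > length(fwd)) stop("at most 5 default barcode pairs")
  data.frame(sample = paste0("S", seq_len(n_samples)),
             fwd = fwd[seq_len(n_samples)], rev = rev[seq_len(n_samples)],
             stringsAsFactors = FALSE)
}

#' Sequencing-error model for the read simulator
#'
#' Per-base i.i.d. substitution, insertion and deletion probabilities, and
#' the Phred-quality distribution of emitted bases (normal with mean
#' `mean_q`, sd `q_sd`, rounded and clamped to \[2, 41\]).  Qualities are
#' drawn independently of the realized errors, as in a well-calibrated but
#' uninformative quality track.  The default approximates a Q20-Q30 CCS
#' profile: 1% total error split 2:1:1 between substitutions and the two
#' indel types.
#'
#' @param sub,ins,del Per-base error rates in \[0, 1\].
#' @param mean_q Target mean Phred score of emitted qualities.
#' @param q_sd Per-base Phred standard deviation (0 = uniform at `mean_q`).
#' @return An `error_model` list.
#' @export
error_model <- function(sub = 0.005, ins = 0.0025, del = 0.0025,
                        mean_q = 27, q_sd = 5) {
  rates <- c(sub = sub, ins = ins, del = del)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  if (sub + del > 1) stop("sub + del must not exceed 1")
  structure(list(sub = sub, ins = ins, del = del,
                 mean_q = mean_q, q_sd = q_sd),
            class = "error_model")
}

#' @rdname error_model
#' @export
zero_error_model <- function(mean_q = 30) {
  error_model(sub = 0, ins = 0, del = 0, mean_q = mean_q, q_sd = 0)
}

#' Junction indel model
#'
#' NHEJ junction indels are drawn as a truncated geometric size distribution
#' with deletions outnumbering insertions 3:1, plus explicit preset events
#' (by default the commonly observed 4-bp downstream and 11-bp upstream
#' junction deletions).  The minimum size (default 3) is chosen one above
#' the classifier's default edit-distance tolerance: smaller junction indels
#' are indistinguishable from sequencing error by the k-mer assay and would
#' be read as unedited.
#'
#' @param p Geometric success parameter for the size distribution.
#' @param min_size,max_size Inclusive size support.
#' @param del_prob Probability that an indel is a deletion (vs insertion).
#' @param presets List of preset events, each `list(size = <signed int>,
#'   where = "upstream"|"downstream"|"straddle")`; negative size = deletion.
#' @param preset_prob Probability of drawing a preset instead of a random
#'   size.
#' @param detect_margin Detectability guard: a drawn indel is accepted only
#'   if the resulting junction differs by more than `detect_margin`
#'   Levenshtein edits from the unedited junction and from the seamless
#'   excision/inversion junctions (otherwise it is redrawn).  This keeps the
#'   simulated event molecularly distinguishable from the intact locus and
#'   from other repair products -- e.g. an inserted run that happens to
#'   duplicate flanking sequence can sit within 2 edits of the unedited
#'   site and would be invisible to any edit-tolerant assay.  0 disables
#'   the guard.
#' @return An `indel_model` list.
#' @export
indel_model <- function(p = 0.3, min_size = 3L, max_size = 27L,
                        del_prob = 0.75,
                        presets = list(list(size = -4L, where = "downstream"),
                                       list(size = -11L, where = "upstream")),
                        preset_prob = 0.25,
                        detect_margin = 2L) {
  stopifnot(p > 0, p < 1, min_size >= 1L, max_size >= min_size,
            del_prob >= 0, del_prob <= 1, preset_prob >= 0, preset_prob <= 1,
            detect_margin >= 0L)
  structure(list(p = p, min_size = as.integer(min_size),
                 max_size = as.integer(max_size), del_prob = del_prob,
                 presets = presets, preset_prob = preset_prob,
                 detect_margin = as.integer(detect_margin)),
            class = "indel_model")
}

#' Simulation configuration
#'
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed; the generator is bit-exact reproducible.
#' @param proportions Named category proportions over the truth vocabulary
#'   (no `unclassified`); must sum to 1 within 1e-9.  Defaults to the
#'   midpoints of the reported per-library outcome ranges.
#' @param indels An [indel_model()].
#' @param errors An [error_model()].
#' @param barcode_pairs Data frame with columns `sample`, `fwd`, `rev`
#'   (8-mer barcodes); reads are assigned to samples uniformly.
#' @param aav List controlling AAV fragment insertion: `min_len`, `max_len`
#'   (uniform fragment length, default 100-1600 nt), `orientation_prob`
#'   (probability of reverse orientation), `max_total` (cap on the total
#'   molecule length so the template stays PCR-amplifiable, default 1700 nt).
#' @param delta_indel_prob Probability that a productive-excision molecule
#'   carries a junction indel at the fusion seam (default 0: seamless
#'   repair, the dominant observed product).
#' @param revcomp_prob Probability a read is emitted reverse-complemented.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reads = 5000L, seed = 1L,
                       proportions = default_proportions(),
                       indels = indel_model(),
                       errors = error_model(),
                       barcode_pairs = default_barcode_pairs(1L),
                       aav = list(min_len = 100L, max_len = 1600L,
                                  orientation_prob = 0.5, max_total = 1700L),
                       delta_indel_prob = 0,
                       revcomp_prob = 0.5) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  bad <- setdiff(names(proportions),
                 setdiff(outcome_categories(), "unclassified"))
  if (length(bad)) stop("unknown category in proportions: ",
                        paste(bad, collapse = ", "))
  if (any(proportions < 0)) stop("proportions must be non-negative")
  stopifnot(is.data.frame(barcode_pairs),
            all(c("sample", "fwd", "rev") %in% names(barcode_pairs)))
  check_barcode_distances(barcode_pairs, min_dist = 1L)
  if (aav$min_len < 25L) stop("AAV fragment min_len must be >= 25")
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 proportions = proportions, indels = indels, errors = errors,
                 barcode_pairs = barcode_pairs, aav = aav,
                 delta_indel_prob = delta_indel_prob,
                 revcomp_prob = revcomp_prob),
            class = "sim_config")
}

# all pooled barcodes pairwise distinct at Hamming distance > 2 * max_mismatch
check_barcode_distances <- function(pairs, min_dist = 1L) {
  bcs <- c(pairs$fwd, pairs$rev)
  if (any(nchar(bcs) != nchar(bcs[1])))
    stop("barcodes must all have equal length")
  n <- length(bcs)
  if (n < 2L) return(invisible(TRUE))
  m <- do.call(rbind, strsplit(bcs, "", fixed = TRUE))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (sum(m[i, ] != m[j, ]) <= 2L * min_dist)
      stop("barcode collision: '", bcs[i], "' and '", bcs[j],
           "' are within Hamming distance ", 2L * min_dist)
  }
  invisible(TRUE)
}

#' Apply sequencing errors to a molecule
#'
#' Per-base i.i.d. substitutions (always to a different base), deletions,
#' and single-base insertions at each inter-base gap, with Phred qualities
#' drawn per emitted base from the error model's quality distribution.
#'
#' @param seq A DNA string.
#' @param errors An [error_model()].
#' @return List with `bases` (mutated sequence) and `qual` (Phred+33 string
#'   of equal length).
#' @export
apply_errors <- function(seq, errors) {
  stopifnot(inherits(errors, "error_model"))
  b <- charToRaw(seq)      # byte-level editing: ~10x faster than strsplit
  n <- length(b)
  if (errors$sub > 0 || errors$del > 0) {
    u <- runif(n)
    is_sub <- u < errors$sub
    is_del <- !is_sub & u < errors$sub + errors$del
    if (any(is_sub)) {
      base_idx <- match(b[is_sub], .acgt_raw)
      pick <- sample.int(3L, sum(is_sub), replace = TRUE)
      b[is_sub] <- .alt_raw[(base_idx - 1L) * 3L + pick]
    }
    if (any(is_del)) b <- b[!is_del]
  }
  if (errors$ins > 0 && length(b) > 0L) {
    gaps <- which(runif(length(b) + 1L) < errors$ins)  # gap g = before base g
    if (length(gaps)) {
      newb <- .acgt_raw[sample.int(4L, length(gaps), replace = TRUE)]
      out <- raw(length(b) + length(gaps))
      pos <- gaps + seq_along(gaps) - 1L  # target indices of insertions
      out[pos] <- newb
      out[-pos] <- b
      b <- out
    }
  }
  n_out <- length(b)
  q <- if (errors$q_sd > 0) {
    pmin(41L, pmax(2L, as.integer(round(rnorm(n_out, errors$mean_q, errors$q_sd)))))
  } else rep(as.integer(round(errors$mean_q)), n_out)
  list(bases = rawToChar(b),
       qual = rawToChar(as.raw(q + 33L)))
}

.acgt_raw <- charToRaw("ACGT")
# alternatives per base, 3 each: A->CGT, C->AGT, G->ACT, T->ACG
.alt_raw <- charToRaw("CGTAGTACTACG")

# a single junction indel at inter-base position pos; negative size =
# deletion, positive = insertion of random bases
apply_junction_indel <- function(seq, pos, size,
                                 where = c("straddle", "upstream", "downstream")) {
  where <- match.arg(where)
  n <- nchar(seq)
  if (size < 0L) {
    s <- -size
    off <- switch(where,
                  upstream = -s,
                  downstream = 0L,
                  straddle = as.integer(sample.int(s + 1L, 1L) - 1L - s))
    from <- max(0L, pos + off)           # inter-base start of deleted run
    to <- min(n, from + s)
    paste0(substr(seq, 1L, from), substr(seq, to + 1L, n))
  } else {
    paste0(substr(seq, 1L, pos), random_dna(size), substr(seq, pos + 1L, n))
  }
}

# staggered k-mers spanning inter-base position pos on seq (detectability
# guard; mirrors the classifier's junction-centred feature convention)
guard_kmers <- function(seq, pos, k = 25L, shifts = c(-4L, 0L, 4L)) {
  starts <- pos - k %/% 2L + shifts
  starts <- starts[starts >= 0L & starts + k <= nchar(seq)]
  unique(substring(seq, starts + 1L, starts + k))
}

# junction sequences an indel must stay distinguishable from: the unedited
# junction at its own site, plus the seamless excision and inversion seams
locus_guards <- function(locus) {
  prods <- expected_products(locus)
  cut5 <- locus$guide5$cut_pos
  cut3 <- locus$guide3$cut_pos
  both <- function(x) c(x, revcomp(x))  # classification is strand-blind
  list(site5 = both(guard_kmers(locus$reference, cut5)),
       site3 = both(guard_kmers(locus$reference, cut3)),
       cross = both(c(guard_kmers(prods$deletion, cut5),
                      guard_kmers(prods$inversion, cut5),
                      guard_kmers(prods$inversion, cut3))))
}

# min infix edit distance of any guard k-mer to the molecule around pos
guard_min_dist <- function(mol, pos, kmers, pad = 50L) {
  win <- substr(mol, max(1L, pos - pad), min(nchar(mol), pos + pad))
  min(adist(kmers, win, partial = TRUE))
}

# draw an indel at pos until the junction is detectably disrupted
draw_guarded_indel <- function(seq, pos, im, site_kmers, cross_kmers) {
  for (attempt in seq_len(100L)) {
    ind <- draw_indel(im)
    mol <- apply_junction_indel(seq, pos, ind$size, ind$where)
    if (im$detect_margin == 0L) return(list(mol = mol, size = ind$size))
    ok <- guard_min_dist(mol, pos, site_kmers) > im$detect_margin &&
      guard_min_dist(mol, pos, cross_kmers) > im$detect_margin
    if (ok) return(list(mol = mol, size = ind$size))
  }
  stop("could not draw a detectably disruptive junction indel at this site")
}

draw_indel <- function(im) {
  if (length(im$presets) && runif(1) < im$preset_prob) {
    pr <- im$presets[[sample.int(length(im$presets), 1L)]]
    return(list(size = as.integer(pr$size), where = pr$where))
  }
  repeat {
    s <- im$min_size + rgeom(1L, im$p)
    if (s <= im$max_size) break
  }
  sign <- if (runif(1) < im$del_prob) -1L else 1L
  list(size = sign * as.integer(s), where = "straddle")
}

#' Simulate a multiplexed long-read amplicon library
#'
#' Each read's category is drawn i.i.d. from `cfg$proportions`; the molecule
#' is built accordingly (unedited reference; deletion product for productive
#' excision; junction indels at the 5', 3' or both cut sites; inversion
#' product; or an AAV backbone fragment inserted at a cut junction in either
#' orientation), an 8-mer-barcoded primer pair is attached, the read is
#' emitted in random orientation, and sequencing errors with matching Phred
#' strings are applied.  Bit-exact reproducible for a given seed.
#'
#' @param locus A [locus_model()]; AAV integration requires at least one
#'   backbone unless its proportion is 0.
#' @param cfg A [sim_config()].
#' @return A `sim_library`: list with `reads` (a [read_set()]) and `truth`
#'   (data.frame with one row per read: `id`, `sample`, `category`,
#'   `orientation`, indel and AAV fragment descriptors, `molecule_len`).
#' @export
simulate_library <- function(locus, cfg) {
  stopifnot(inherits(locus, "locus_model"), inherits(cfg, "sim_config"))
  if (cfg$proportions["aav_integration"] > 0 && !length(locus$aav_backbones))
    stop("aav_integration proportion > 0 but locus has no AAV backbones")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_reads
  prods <- expected_products(locus)
  cut5 <- locus$guide5$cut_pos
  cut3 <- locus$guide3$cut_pos
  guards <- locus_guards(locus)
  cats <- sample(names(cfg$proportions), n, replace = TRUE,
                 prob = cfg$proportions)
  samp_i <- sample.int(nrow(cfg$barcode_pairs), n, replace = TRUE)
  rc <- runif(n) < cfg$revcomp_prob

  ids <- sprintf("read%06d", seq_len(n))
  bases <- character(n); quals <- character(n)
  t_indel5 <- rep(NA_integer_, n); t_indel3 <- rep(NA_integer_, n)
  t_fus <- rep(NA_integer_, n)
  t_vec <- rep(NA_character_, n); t_start <- rep(NA_integer_, n)
  t_len <- rep(NA_integer_, n); t_orient <- rep(NA_character_, n)
  t_mol <- integer(n)

  bc_fwd <- cfg$barcode_pairs$fwd
  bc_rev_rc <- revcomp(cfg$barcode_pairs$rev)

  for (i in seq_len(n)) {
    mol <- switch(
      cats[i],
      unedited = locus$reference,
      delta_exon = {
        mol <- prods$deletion
        if (cfg$delta_indel_prob > 0 && runif(1) < cfg$delta_indel_prob) {
          ind <- draw_indel(cfg$indels)
          t_fus[i] <- ind$size
          mol <- apply_junction_indel(mol, cut5, ind$size, ind$where)
        }
        mol
      },
      indel5 = {
        ind <- draw_guarded_indel(locus$reference, cut5, cfg$indels,
                                  guards$site5, guards$cross)
        t_indel5[i] <- ind$size
        ind$mol
      },
      indel3 = {
        ind <- draw_guarded_indel(locus$reference, cut3, cfg$indels,
                                  guards$site3, guards$cross)
        t_indel3[i] <- ind$size
        ind$mol
      },
      indel_both = {
        i3 <- draw_guarded_indel(locus$reference, cut3, cfg$indels,
                                 guards$site3, guards$cross)
        i5 <- draw_guarded_indel(i3$mol, cut5, cfg$indels,
                                 guards$site5, guards$cross)
        t_indel3[i] <- i3$size; t_indel5[i] <- i5$size
        i5$mol
      },
      inversion = prods$inversion,
      aav_integration = {
        vec_i <- sample.int(length(locus$aav_backbones), 1L)
        bb <- locus$aav_backbones[[vec_i]]
        base <- if (runif(1) < 0.5) prods$deletion else locus$reference
        L <- as.integer(round(runif(1, cfg$aav$min_len, cfg$aav$max_len)))
        L <- min(L, nchar(bb), max(cfg$aav$min_len,
                                   cfg$aav$max_total - nchar(base)))
        st <- sample.int(nchar(bb) - L + 1L, 1L)
        frag <- substr(bb, st, st + L - 1L)
        orient <- if (runif(1) < cfg$aav$orientation_prob) "rev" else "fwd"
        if (orient == "rev") frag <- revcomp(frag)
        t_vec[i] <- names(locus$aav_backbones)[vec_i]
        t_start[i] <- st; t_len[i] <- L; t_orient[i] <- orient
        paste0(substr(base, 1L, cut5), frag,
               substr(base, cut5 + 1L, nchar(base)))
      },
      stop("unknown category: ", cats[i])
    )
    mol <- paste0(bc_fwd[samp_i[i]], mol, bc_rev_rc[samp_i[i]])
    t_mol[i] <- nchar(mol)
    if (rc[i]) mol <- revcomp(mol)
    er <- apply_errors(mol, cfg$errors)
    bases[i] <- er$bases
    quals[i] <- er$qual
  }

  truth <- data.frame(
    id = ids, sample = cfg$barcode_pairs$sample[samp_i], category = cats,
    orientation = ifelse(rc, "reverse", "forward"),
    indel5 = t_indel5, indel3 = t_indel3, indel_fusion = t_fus,
    aav_vector = t_vec, aav_start = t_start,
    aav_len = t_len, aav_orient = t_orient,
    molecule_len = t_mol, stringsAsFactors = FALSE)

  structure(list(reads = read_set(ids, bases, quals), truth = truth,
                 config = cfg),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d reads, seed %d\n",
              nrow(x$truth), x$config$seed))
  print(round(100 * table(x$truth$category) / nrow(x$truth), 3))
  invisible(x)
}

#' Write a simulated library to FASTQ plus a truth TSV
#'
#' @param sim A [simulate_library()] result.
#' @param fastq_path,truth_path Output paths.
#' @export
write_sim_library <- function(sim, fastq_path, truth_path) {
  stopifnot(inherits(sim, "sim_library"))
  write_fastq(sim$reads, fastq_path)
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fastq_path, truth_path))
}

#' Construct the default synthetic study locus
#'
#' Generates a random 833-bp amplicon with two embedded SaCas9 guide sites
#' (inter-cut distance 387 bp, so the productive deletion product is 446 bp),
#' a 213-bp exon between the cuts, and two synthetic AAV vector backbones
#' (2,000 and 1,800 bp).  The 5' guide lies on the plus strand and the 3'
#' guide on the minus strand, each with a valid NNGRRT PAM.  Deterministic
#' for a given seed; sequences are resampled until the guides are unique and
#' the derived feature set is diagnostic.
#'
#' @param seed Integer seed.
#' @param len Amplicon length (default 833).
#' @param cut5,cut3 Inter-base cut positions (defaults 200 and 587).
#' @param exon 1-based inclusive exon interval (default `c(261, 473)`).
#' @return A [locus_model()] with AAV backbones attached.
#' @export
synthetic_locus <- function(seed = 1L, len = 833L, cut5 = 200L, cut3 = 587L,
                            exon = c(261L, 473L)) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  for (attempt in seq_len(50L)) {
    set.seed(seed + (attempt - 1L) * 1000L)
    ref <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
    # 5' guide, plus strand: protospacer [cut5-18, cut5+3), PAM [cut5+3, cut5+9)
    # (1-based); NNGRRT constraint at PAM positions 3-6
    pam5 <- cut5 + 4L  # 1-based PAM start
    ref[pam5 + 2L] <- "G"
    ref[pam5 + 3L] <- sample(c("A", "G"), 1L)
    ref[pam5 + 4L] <- sample(c("A", "G"), 1L)
    ref[pam5 + 5L] <- "T"
    # 3' guide, minus strand: match [cut3-2, cut3+19), PAM on ref is
    # revcomp(NNGRRT) = AYYCNN immediately 5' of the match
    pam3 <- cut3 - 8L  # 1-based start of the 6-base revcomp PAM
    ref[pam3] <- "A"
    ref[pam3 + 1L] <- sample(c("C", "T"), 1L)
    ref[pam3 + 2L] <- sample(c("C", "T"), 1L)
    ref[pam3 + 3L] <- "C"
    refs <- paste(ref, collapse = "")
    proto5 <- substr(refs, cut5 - 17L, cut5 + 3L)          # 21 nt, + strand
    proto3 <- revcomp(substr(refs, cut3 - 2L, cut3 + 18L)) # 21 nt, - strand
    aav <- c(SaCas9_AAV = random_dna(2000L), sgRNA_AAV = random_dna(1800L))

    loc <- tryCatch({
      g5 <- find_guide_site(refs, proto5, "guide5")
      g3 <- find_guide_site(refs, proto3, "guide3")
      stopifnot(g5$cut_pos == cut5, g3$cut_pos == cut3)
      l <- locus_model(refs, exon, g5, g3, aav_backbones = aav)
      # diagnosticity check across the default optimization grid
      derive_features(l, k = 25L)
      derive_features(l, k = 17L)
      l
    }, error = function(e) NULL)
    if (!is.null(loc)) return(loc)
  }
  stop("could not construct a valid synthetic locus from this seed")
}
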