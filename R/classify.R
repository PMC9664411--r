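# The editing-outcome caller: feature presence -> category via a fixed
# precedence, plus whole-library classification and control-library
# parameter optimization.

# presence: named logical vector over feature names -> category label.
# Precedence (most specific evidence first):
#   1. any AAV backbone k-mer        -> aav_integration
#   2. any inversion junction        -> inversion
#   3. fusion seam, no exon sequence -> delta_exon
#   4. exon present, both cut sites disrupted -> indel_both
#   5. only the 5' site disrupted    -> indel5
#   6. only the 3' site disrupted    -> indel3
#   7. both cut sites intact         -> unedited
#   otherwise                        -> unclassified
decide_category <- function(has) {
  hit <- function(nm) isTRUE(unname(has[nm])[1])
  aav <- any(has[grepl("^aav:", names(has))])
  inv <- hit("inversion_left") || hit("inversion_right")
  fus <- hit("fusion")
  exo <- hit("exon_internal")
  i5 <- hit("intact5")
  i3 <- hit("intact3")
  if (aav) return("aav_integration")
  if (inv) return("inversion")
  if (fus && !exo) return("delta_exon")
  if (exo && !i5 && !i3) return("indel_both")
  if (!i5 && i3) return("indel5")
  if (i5 && !i3) return("indel3")
  if (i5 && i3) return("unedited")
  "unclassified"
}

#' Classify a single read from its feature hits
#'
#' Applies the fixed category precedence to the feature evidence of one
#' read: AAV backbone evidence dominates (backbone k-mers are absent from
#' the locus, hence most specific), then inversion junctions (inversions
#' retain exon sequence), then the fusion seam of productive excision,
#' then disrupted-cut-site logic, with `unedited` requiring both intact-site
#' features and anything else falling to `unclassified`.
#'
#' @param hits A data.frame of [match_features()] hits for one read, or a
#'   character vector of hit feature names.
#' @param read_id Optional identifier recorded in the result.
#' @param read_length Optional read length recorded in the result.
#' @return A `classification_result`: list with `id`, `category`, `evidence`
#'   (the hits), `read_length`.
#' @export
classify_read <- function(hits, read_id = NA_character_,
                          read_length = NA_integer_) {
  feats <- if (is.data.frame(hits)) unique(hits$feature) else unique(hits)
  has <- setNames(rep(TRUE, length(feats)), feats)
  structure(list(id = read_id,
                 category = decide_category(has),
                 evidence = hits,
                 read_length = read_length),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  ev <- if (is.data.frame(x$evidence)) x$evidence$feature else x$evidence
  cat(sprintf("<classification_result> %s -> %s [%s]\n",
              x$id, x$category, paste(ev, collapse = ", ")))
  invisible(x)
}

#' Classify every read in a library
#'
#' Runs feature matching ([match_features()]) and the fixed-precedence
#' category call on each read, returning per-read calls and a per-sample
#' category table over the fixed eight-category partition (percentages are
#' computed over all classified reads, including `unclassified`).
#'
#' @param reads A [read_set()] (or character vector of sequences).
#' @param fs A [derive_features()] feature set.
#' @param max_dist Override of the feature set's matching tolerance.
#' @param sample Sample label recorded in the category table.
#' @return List with `calls` (data.frame: `id`, `category`, `evidence`
#'   comma-separated summary, `read_length`) and `table` (a
#'   [category_table()]).
#' @export
classify_library <- function(reads, fs, max_dist = fs$max_dist,
                             sample = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  if (is.character(reads)) reads <- read_set(
    if (!is.null(names(reads))) names(reads) else as.character(seq_along(reads)),
    reads, vapply(nchar(reads), function(n) int_to_phred(rep(30L, n)), character(1)))
  if (is.null(sample)) {
    sample <- if (nrow(reads) && !all(is.na(reads$sample)))
      paste(unique(reads$sample), collapse = ",") else "(all)"
  }
  if (nrow(reads) == 0L) {
    warning("empty input: no reads to classify")
    calls <- data.frame(id = character(0), category = character(0),
                        evidence = character(0), read_length = integer(0),
                        stringsAsFactors = FALSE)
    return(list(calls = calls, table = category_table(calls, sample = sample)))
  }

  hm <- match_matrix(reads, fs, max_dist)
  present <- !is.na(hm$dist)               # reads x features
  feats <- colnames(hm$dist)
  aav_cols <- grepl("^aav:", feats)

  aav <- if (any(aav_cols)) rowSums(present[, aav_cols, drop = FALSE]) > 0L else
    rep(FALSE, nrow(present))
  inv <- present[, "inversion_left"] | present[, "inversion_right"]
  fus <- present[, "fusion"]
  exo <- present[, "exon_internal"]
  i5 <- present[, "intact5"]
  i3 <- present[, "intact3"]

  category <- rep("unclassified", nrow(present))
  category[i5 & i3] <- "unedited"
  category[i5 & !i3] <- "indel3"
  category[!i5 & i3] <- "indel5"
  category[exo & !i5 & !i3] <- "indel_both"
  category[fus & !exo] <- "delta_exon"
  category[inv] <- "inversion"
  category[aav] <- "aav_integration"

  evidence <- apply(present, 1L, function(p) paste(feats[p], collapse = ","))
  calls <- data.frame(id = hm$ids, category = category,
                      evidence = evidence,
                      read_length = nchar(reads$bases),
                      stringsAsFactors = FALSE)
  list(calls = calls, table = category_table(calls, sample = sample))
}

#' Per-sample category count/percentage table
#'
#' @param calls Per-read calls (data.frame with a `category` column).
#' @param sample Sample label.
#' @return A `category_table` data.frame: `sample`, `category`, `count`,
#'   `percent` (over all classified reads, including `unclassified`), one
#'   row per category of [outcome_categories()].
#' @export
category_table <- function(calls, sample = "(all)") {
  cats <- outcome_categories()
  count <- vapply(cats, function(cc) sum(calls$category == cc), integer(1))
  total <- nrow(calls)
  tab <- data.frame(sample = sample, category = cats, count = count,
                    percent = if (total) 100 * count / total else rep(NA_real_, length(cats)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "total") <- total
  class(tab) <- c("category_table", "data.frame")
  tab
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("<category_table> sample %s, %d reads\n",
              x$sample[1], attr(x, "total")))
  y <- as.data.frame(x)
  y$percent <- format_percent(y$percent)
  print(y, row.names = FALSE)
  invisible(x)
}

# 2 decimals, 4 decimals below 0.01%
format_percent <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p > 0 & p < 0.01, sprintf("%.4f", p), sprintf("%.2f", p)))
}

#' Optimize matching parameters against an untreated control library
#'
#' Evaluates every (k, max_dist) grid cell by classifying an unedited
#' control library and measuring the fraction of reads assigned to any
#' non-`unedited` category (the false-positive rate).  Returns the arg-min,
#' ties broken toward larger `max_dist` (more sequencing-error tolerance)
#' and then smaller `k`.
#'
#' @param control A [read_set()] of untreated/unedited control reads
#'   (already demultiplexed and filtered).
#' @param locus A [locus_model()].
#' @param k_grid,dist_grid Candidate k-mer lengths and edit distances.
#' @param ... Passed to [derive_features()] (e.g. `n_per_junction`,
#'   `aav_stride`).
#' @return List with `k`, `max_dist`, and `diagnostics` (data.frame with one
#'   row per grid cell: `k`, `max_dist`, `objective`, per-category
#'   false-positive percentages).
#' @export
optimize_params <- function(control, locus, k_grid = c(17L, 25L),
                            dist_grid = 0:2, ...) {
  if (length(k_grid) == 0L || length(dist_grid) == 0L)
    stop("empty parameter grid")
  rows <- list()
  for (k in sort(as.integer(k_grid))) {
    fs <- derive_features(locus, k = k, max_dist = max(dist_grid), ...)
    for (d in sort(as.integer(dist_grid))) {
      res <- classify_library(control, fs, max_dist = d)
      tab <- res$table
      obj <- sum(tab$count[tab$category != "unedited"]) / max(1L, attr(tab, "total"))
      row <- data.frame(k = k, max_dist = d, objective = obj,
                        stringsAsFactors = FALSE)
      for (cc in setdiff(outcome_categories(), "unedited"))
        row[[paste0("pct_", cc)]] <- tab$percent[tab$category == cc]
      rows[[length(rows) + 1L]] <- row
    }
  }
  diag <- do.call(rbind, rows)
  # arg-min objective; ties -> larger max_dist, then smaller k
  ord <- order(diag$objective, -diag$max_dist, diag$k)
  best <- diag[ord[1L], ]
  list(k = best$k, max_dist = best$max_dist, diagnostics = diag)
}
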