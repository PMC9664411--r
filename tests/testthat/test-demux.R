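test_that("exact barcode pairs are assigned, oriented, and trimmed", {
  pairs <- dualguide:::default_barcode_pairs(2L)
  set.seed(30)
  insert <- rdna(120)
  fwd_read <- paste0(pairs$fwd[1], insert, rc(pairs$rev[1]))
  rev_read <- rc(fwd_read)
  rs <- read_set(c("f", "r"), c(fwd_read, rev_read),
                 vapply(nchar(c(fwd_read, rev_read)),
                        function(n) int_to_phred(rep(30L, n)), character(1)))
  dm <- demultiplex(rs, pairs)
  s1 <- dm$samples$S1
  expect_equal(nrow(s1), 2L)
  expect_equal(s1$orientation, c("forward", "reverse"))
  expect_equal(s1$bases[1], insert)
  expect_equal(s1$bases[2], rc(insert))
  expect_equal(nrow(dm$samples$S2), 0L)
  expect_equal(nrow(dm$unassigned), 0L)
})

test_that("one barcode mismatch is tolerated, more is unassigned", {
  pairs <- dualguide:::default_barcode_pairs(1L)
  set.seed(31)
  insert <- rdna(100)
  bc1 <- mutate_subs(pairs$fwd[1], 1L)
  bc2 <- mutate_subs(pairs$fwd[1], 2L)
  mk <- function(f) paste0(f, insert, rc(pairs$rev[1]))
  rs <- read_set(c("a", "b"), c(mk(bc1), mk(bc2)),
                 vapply(nchar(c(mk(bc1), mk(bc2))),
                        function(n) int_to_phred(rep(30L, n)), character(1)))
  dm <- demultiplex(rs, pairs, max_mismatch = 1L)
  expect_equal(dm$samples$S1$id, "a")
  expect_equal(dm$unassigned$id, "b")
})

test_that("demultiplexing a noisy multiplexed library recovers >= 99% of assignments", {
  loc <- study_locus()
  pairs <- dualguide:::default_barcode_pairs(5L)
  cfg <- sim_config(n_reads = 1000L, seed = 77L,
                    barcode_pairs = pairs,
                    errors = error_model(sub = 0.01, ins = 0, del = 0,
                                         mean_q = 27, q_sd = 3))
  sim <- simulate_library(loc, cfg)
  dm <- demultiplex(sim$reads, pairs, max_mismatch = 1L)
  assigned <- do.call(rbind, lapply(names(dm$samples), function(s) {
    if (nrow(dm$samples[[s]]) == 0L) return(NULL)
    data.frame(id = dm$samples[[s]]$id, sample = s,
               orientation = dm$samples[[s]]$orientation)
  }))
  truth <- sim$truth
  correct <- sum(truth$sample[match(assigned$id, truth$id)] == assigned$sample)
  expect_gte(correct / nrow(truth), 0.99)
  # no cross-sample misassignment among assigned reads
  expect_equal(correct, nrow(assigned))
  # orientation flags match the emission orientation
  expect_equal(assigned$orientation,
               truth$orientation[match(assigned$id, truth$id)])
})

test_that("every input read lands in exactly one demultiplexing bucket", {
  loc <- study_locus()
  pairs <- dualguide:::default_barcode_pairs(3L)
  cfg <- sim_config(n_reads = 400L, seed = 55L, barcode_pairs = pairs)
  sim <- simulate_library(loc, cfg)
  dm <- demultiplex(sim$reads, pairs)
  ids <- c(unlist(lapply(dm$samples, `[[`, "id"), use.names = FALSE),
           dm$unassigned$id)
  expect_equal(sort(ids), sort(sim$reads$id))
  expect_equal(anyDuplicated(ids), 0L)
  rep <- dm$report
  expect_equal(rep$input[rep$sample == "(unassigned)"],
               sum(rep$demuxed, na.rm = TRUE) +
                 rep$failed_barcode[rep$sample == "(unassigned)"])
})

test_that("barcode sets closer than the guaranteed separation are rejected", {
  pairs <- data.frame(sample = c("a", "b"),
                      fwd = c("AAAACTCC", "AAAACTCA"),
                      rev = c("TACAATTA", "ACTGTATA"))
  rs <- read_set("x", "ACGTACGT", int_to_phred(rep(30L, 8)))
  expect_error(demultiplex(rs, pairs, max_mismatch = 1L), "barcode collision")
})

test_that("length filtering is boundary-inclusive after trimming", {
  mk <- function(len, q) read_set(paste0("r", len),
                                  strrep("A", len),
                                  int_to_phred(rep(q, len)))
  short <- quality_length_filter(mk(399L, 30L))
  expect_equal(nrow(short$passed), 0L)
  expect_equal(short$report$failed_length, 1L)
  exact <- quality_length_filter(mk(400L, 20L))
  expect_equal(nrow(exact$passed), 1L)
})

test_that("mean quality uses the error-probability scale", {
  # half Q30, half Q10: mean error prob (1e-3 + 1e-1)/2 -> Q ~ 12.97
  q <- c(rep(30L, 200), rep(10L, 200))
  expect_equal(mean_quality(q), -10 * log10(mean(10^(-q / 10))))
  expect_equal(round(mean_quality(q), 2), 12.97)
  expect_equal(mean_quality(q, method = "phred"), 20)
  rs <- read_set("r", strrep("A", 400), int_to_phred(q))
  flt <- quality_length_filter(rs, min_mean_q = 20)
  expect_equal(nrow(flt$passed), 0L)
  expect_equal(flt$report$failed_maq, 1L)
  # the same read passes under arithmetic-mean semantics
  flt2 <- quality_length_filter(rs, min_mean_q = 20, maq_method = "phred")
  expect_equal(nrow(flt2$passed), 1L)
})

test_that("filtering is orientation-invariant and idempotent", {
  loc <- study_locus()
  cfg <- sim_config(n_reads = 200L, seed = 60L)
  sim <- simulate_library(loc, cfg)
  f1 <- quality_length_filter(sim$reads)
  # reverse-complementing every read leaves the decisions unchanged
  rc_reads <- read_set(sim$reads$id, rc(sim$reads$bases),
                       vapply(strsplit(sim$reads$qual, ""), function(ch)
                         paste(rev(ch), collapse = ""), character(1)))
  f2 <- quality_length_filter(rc_reads)
  expect_equal(f1$passed$id, f2$passed$id)
  # idempotence
  f3 <- quality_length_filter(f1$passed)
  expect_equal(f3$passed, f1$passed)
  expect_equal(f3$report$failed_maq + f3$report$failed_length, 0L)
})

test_that("the combined demux + filter report reconciles all counts", {
  loc <- study_locus()
  pairs <- dualguide:::default_barcode_pairs(2L)
  cfg <- sim_config(n_reads = 500L, seed = 61L, barcode_pairs = pairs)
  sim <- simulate_library(loc, cfg)
  dm <- demultiplex(sim$reads, pairs)
  df <- demux_filter(dm, min_mean_q = 20, min_len = 400L)
  rep <- df$report
  pool <- rep[rep$sample == "(pool)", ]
  expect_equal(pool$input, 500L)
  expect_equal(pool$input, pool$demuxed + pool$failed_barcode)
  per <- rep[rep$sample != "(pool)", ]
  expect_equal(per$demuxed, per$passed + per$failed_maq + per$failed_length)
  expect_equal(sum(vapply(df$samples, nrow, integer(1))), sum(per$passed))
})
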