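test_that("an error-free unedited-only library reproduces the barcoded reference", {
  loc <- study_locus()
  cfg <- sim_config(n_reads = 20L, seed = 5L,
                    proportions = c(unedited = 1),
                    errors = zero_error_model(),
                    revcomp_prob = 0)
  sim <- simulate_library(loc, cfg)
  bc <- cfg$barcode_pairs[1, ]
  want <- paste0(bc$fwd, loc$reference, rc(bc$rev))
  expect_true(all(sim$reads$bases == want))
  expect_true(all(nchar(sim$reads$qual) == nchar(want)))
  expect_true(all(sim$truth$category == "unedited"))

  # reverse-complement emission flips the whole barcoded molecule
  cfg_rc <- sim_config(n_reads = 10L, seed = 6L,
                       proportions = c(unedited = 1),
                       errors = zero_error_model(), revcomp_prob = 1)
  sim_rc <- simulate_library(loc, cfg_rc)
  expect_true(all(sim_rc$reads$bases == rc(want)))
  expect_true(all(sim_rc$truth$orientation == "reverse"))
})

test_that("simulation is bit-exact reproducible for a given seed", {
  loc <- study_locus()
  cfg <- sim_config(n_reads = 300L, seed = 99L)
  s1 <- simulate_library(loc, cfg)
  s2 <- simulate_library(loc, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fastq"); f2 <- file.path(dir, "b.fastq")
  write_sim_library(s1, f1, file.path(dir, "a.tsv"))
  write_sim_library(s2, f2, file.path(dir, "b.tsv"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  s3 <- simulate_library(loc, sim_config(n_reads = 300L, seed = 100L))
  expect_false(identical(s1$reads$bases, s3$reads$bases))
})

test_that("truth table and FASTQ agree on read ids, one row per read", {
  loc <- study_locus()
  sim <- simulate_library(loc, sim_config(n_reads = 200L, seed = 3L))
  expect_equal(sim$truth$id, sim$reads$id)
  expect_equal(anyDuplicated(sim$truth$id), 0L)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "lib.fastq")
  write_sim_library(sim, fq, file.path(dir, "truth.tsv"))
  back <- read_fastq(fq)
  expect_equal(back$id, sim$truth$id)
  expect_equal(back$bases, sim$reads$bases)
  expect_equal(back$qual, sim$reads$qual)
})

test_that("category draws follow the configured proportions", {
  loc <- study_locus()
  n <- 5000L
  cfg <- sim_config(n_reads = n, seed = 42L)
  sim <- simulate_library(loc, cfg)
  p <- cfg$proportions
  obs <- table(factor(sim$truth$category, levels = names(p))) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(obs - p) <= 3 * se + 1e-12))
})

test_that("apply_errors with zero rates is the identity with uniform qualities", {
  withr::local_seed(1)
  s <- rdna(500)
  out <- apply_errors(s, zero_error_model(mean_q = 30))
  expect_equal(out$bases, s)
  expect_equal(unique(phred_to_int(out$qual)), 30L)
  expect_equal(nchar(out$qual), 500L)
})

test_that("substitution and deletion rates are realized at the configured frequency", {
  withr::local_seed(2)
  s <- rdna(100000)
  out <- apply_errors(s, error_model(sub = 0.01, ins = 0, del = 0,
                                     mean_q = 25, q_sd = 3))
  expect_equal(nchar(out$bases), nchar(s))
  mism <- mean(strsplit(out$bases, "")[[1]] != strsplit(s, "")[[1]])
  expect_lt(abs(mism - 0.01), 3 * sqrt(0.01 * 0.99 / 100000))
  expect_lt(abs(mean(phred_to_int(out$qual)) - 25), 0.5)

  s2 <- rdna(1000)
  out2 <- apply_errors(s2, error_model(sub = 0, ins = 0, del = 0.5))
  expect_lt(abs(nchar(out2$bases) - 500), 3 * sqrt(1000 * 0.25))
  expect_equal(nchar(out2$qual), nchar(out2$bases))

  out3 <- apply_errors(s2, error_model(sub = 0, ins = 0.05, del = 0))
  gain <- nchar(out3$bases) - 1000
  expect_lt(abs(gain - 0.05 * 1001), 3 * sqrt(1001 * 0.05 * 0.95))
})

test_that("error-free molecules carry their category's diagnostic features verbatim", {
  loc <- study_locus()
  fs <- derive_features(loc)
  cfg <- sim_config(
    n_reads = 140L, seed = 8L,
    proportions = setNames(rep(1 / 7, 7),
                           setdiff(outcome_categories(), "unclassified")),
    errors = zero_error_model())
  sim <- simulate_library(loc, cfg)
  required <- list(
    unedited = "intact5", delta_exon = "fusion", inversion = "inversion_left",
    indel5 = "intact3", indel3 = "intact5", indel_both = "exon_internal")
  for (i in seq_len(nrow(sim$truth))) {
    hits <- match_features(sim$reads$bases[i], fs)
    cat_i <- sim$truth$category[i]
    if (cat_i == "aav_integration") {
      expect_true(any(grepl("^aav:", hits$feature)), label = paste("read", i))
      expect_equal(min(hits$dist[grepl("^aav:", hits$feature)]), 0L)
    } else {
      expect_true(required[[cat_i]] %in% hits$feature, label = paste("read", i))
      expect_equal(hits$dist[hits$feature == required[[cat_i]]], 0L)
    }
  }
})

test_that("junction indels honour presets and the size floor", {
  loc <- study_locus()
  cut5 <- loc$guide5$cut_pos
  ref <- loc$reference
  # preset-only model: every indel5 is a -4 downstream or -11 upstream deletion
  im <- indel_model(presets = list(list(size = -4L, where = "downstream"),
                                   list(size = -11L, where = "upstream")),
                    preset_prob = 1)
  cfg <- sim_config(n_reads = 60L, seed = 13L,
                    proportions = c(indel5 = 1), indels = im,
                    errors = zero_error_model(), revcomp_prob = 0)
  sim <- simulate_library(loc, cfg)
  expect_true(all(sim$truth$indel5 %in% c(-4L, -11L)))
  bc <- cfg$barcode_pairs[1, ]
  down <- paste0(bc$fwd, substr(ref, 1, cut5),
                 substr(ref, cut5 + 5, nchar(ref)), rc(bc$rev))
  up <- paste0(bc$fwd, substr(ref, 1, cut5 - 11),
               substr(ref, cut5 + 1, nchar(ref)), rc(bc$rev))
  expect_true(all(ifelse(sim$truth$indel5 == -4L,
                         sim$reads$bases == down, sim$reads$bases == up)))

  # random draws respect the configured size support
  cfg2 <- sim_config(n_reads = 200L, seed = 14L,
                     proportions = c(indel5 = 0.5, indel3 = 0.5),
                     indels = indel_model(preset_prob = 0),
                     errors = zero_error_model())
  sim2 <- simulate_library(loc, cfg2)
  sizes <- abs(c(sim2$truth$indel5, sim2$truth$indel3))
  sizes <- sizes[!is.na(sizes)]
  expect_true(all(sizes >= 3L & sizes <= 27L))
  signs <- sign(c(sim2$truth$indel5, sim2$truth$indel3))
  signs <- signs[!is.na(signs)]
  expect_gt(mean(signs < 0), 0.5)  # deletions dominate 3:1
})

test_that("AAV fragments respect length bounds, orientation, and the template cap", {
  loc <- study_locus()
  cfg <- sim_config(n_reads = 120L, seed = 15L,
                    proportions = c(aav_integration = 1),
                    errors = zero_error_model(), revcomp_prob = 0)
  sim <- simulate_library(loc, cfg)
  tr <- sim$truth
  expect_true(all(tr$aav_len >= 100L & tr$aav_len <= 1600L))
  expect_true(all(tr$aav_vector %in% names(loc$aav_backbones)))
  expect_true(all(tr$molecule_len <= 1700L + 16L))
  expect_true(all(c("fwd", "rev") %in% tr$aav_orient))
  for (i in 1:10) {
    bb <- loc$aav_backbones[[tr$aav_vector[i]]]
    frag <- substr(bb, tr$aav_start[i], tr$aav_start[i] + tr$aav_len[i] - 1L)
    if (tr$aav_orient[i] == "rev") frag <- rc(frag)
    expect_true(grepl(frag, sim$reads$bases[i], fixed = TRUE))
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(proportions = c(unedited = 0.9)), "sum to 1")
  expect_error(sim_config(proportions = c(unedited = 0.5, weird = 0.5)),
               "unknown category")
  bad_bc <- data.frame(sample = c("a", "b"),
                       fwd = c("AAAAAAAA", "AAAAAAAT"),
                       rev = c("CCCCCCCC", "GGGGGGGG"))
  expect_error(sim_config(barcode_pairs = bad_bc), "barcode collision")
  loc <- study_locus()
  no_aav <- locus_model(loc$reference, loc$exon, loc$guide5, loc$guide3)
  expect_error(
    simulate_library(no_aav, sim_config(n_reads = 5L, seed = 1L)),
    "no AAV backbones")
})
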