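test_that("the fixed category precedence resolves every evidence pattern", {
  cases <- list(
    list(hits = c("intact5", "intact3", "exon_internal"), want = "unedited"),
    list(hits = c("fusion"), want = "delta_exon"),
    list(hits = c("aav:SaCas9_AAV:fwd", "fusion"), want = "aav_integration"),
    list(hits = c("exon_internal", "intact3"), want = "indel5"),
    list(hits = c("exon_internal", "intact5"), want = "indel3"),
    list(hits = c("exon_internal"), want = "indel_both"),
    list(hits = c("inversion_left", "exon_internal"), want = "inversion"),
    list(hits = c("inversion_right", "intact5", "intact3"), want = "inversion"),
    list(hits = c("aav:sgRNA_AAV:rev", "inversion_left", "intact5", "intact3"),
         want = "aav_integration"),
    list(hits = c("fusion", "exon_internal", "intact3"), want = "indel5"),
    list(hits = character(0), want = "unclassified"),
    list(hits = c("intact5", "intact3"), want = "unedited")
  )
  for (cs in cases) {
    got <- classify_read(cs$hits, read_id = "r")
    expect_equal(got$category, cs$want,
                 label = paste("hits:", paste(cs$hits, collapse = "+")))
  }
})

test_that("an 11-bp deletion at the 5' cut site is called indel5", {
  loc <- study_locus()
  fs <- derive_features(loc)
  ref <- loc$reference
  cut5 <- loc$guide5$cut_pos
  # independently assembled molecule: 11 bases immediately 5' of the cut gone
  mol <- paste0(substr(ref, 1, cut5 - 11), substr(ref, cut5 + 1, nchar(ref)))
  res <- classify_library(c(r1 = mol), fs)
  expect_equal(res$calls$category, "indel5")
  hits <- match_features(mol, fs)
  expect_false("intact5" %in% hits$feature)
  expect_true(all(c("intact3", "exon_internal") %in% hits$feature))
})

test_that("junction indels below the edit tolerance are read as unedited", {
  loc <- study_locus()
  fs <- derive_features(loc)
  ref <- loc$reference
  cut5 <- loc$guide5$cut_pos
  mol2 <- paste0(substr(ref, 1, cut5 - 2), substr(ref, cut5 + 1, nchar(ref)))
  expect_equal(classify_library(c(r = mol2), fs)$calls$category, "unedited")
})

test_that("excision products with junction indels beyond tolerance become unclassified", {
  loc <- study_locus()
  fs <- derive_features(loc)
  del <- expected_products(loc)$deletion
  cut5 <- loc$guide5$cut_pos
  mol <- paste0(substr(del, 1, cut5 - 11), substr(del, cut5 + 1, nchar(del)))
  expect_equal(classify_library(c(r = mol), fs)$calls$category, "unclassified")
})

test_that("single-read classification agrees with library classification", {
  loc <- study_locus()
  fs <- derive_features(loc)
  sim <- simulate_library(loc, sim_config(n_reads = 60L, seed = 23L))
  res <- classify_library(sim$reads, fs)
  for (i in seq_len(30L)) {
    single <- classify_read(match_features(sim$reads$bases[i], fs),
                            read_id = sim$reads$id[i])
    expect_equal(single$category, res$calls$category[i],
                 label = sim$reads$id[i])
  }
})

test_that("an error-free library is recovered exactly, category by category", {
  loc <- study_locus()
  fs <- derive_features(loc)
  cfg <- sim_config(n_reads = 700L, seed = 19L, errors = zero_error_model())
  sim <- simulate_library(loc, cfg)
  res <- classify_library(sim$reads, fs)
  expect_equal(res$calls$category,
               sim$truth$category[match(res$calls$id, sim$truth$id)])
})

test_that("an all-unedited library yields zero excision, inversion, and AAV calls", {
  loc <- study_locus()
  fs <- derive_features(loc)
  cfg <- sim_config(n_reads = 500L, seed = 29L,
                    proportions = c(unedited = 1))
  sim <- simulate_library(loc, cfg)
  tab <- classify_library(sim$reads, fs)$table
  for (cc in c("delta_exon", "inversion", "aav_integration"))
    expect_equal(tab$percent[tab$category == cc], 0)
})

test_that("classification partitions the library and percentages sum to 100", {
  loc <- study_locus()
  fs <- derive_features(loc)
  sim <- simulate_library(loc, sim_config(n_reads = 400L, seed = 31L))
  res <- classify_library(sim$reads, fs)
  expect_equal(nrow(res$calls), 400L)
  expect_true(all(res$calls$category %in% outcome_categories()))
  expect_equal(sum(res$table$count), attr(res$table, "total"))
  expect_lt(abs(sum(res$table$percent) - 100), 0.01)
})

test_that("classification is orientation-invariant", {
  loc <- study_locus()
  fs <- derive_features(loc)
  sim <- simulate_library(loc, sim_config(n_reads = 300L, seed = 37L))
  res1 <- classify_library(sim$reads, fs)
  flipped <- read_set(sim$reads$id, rc(sim$reads$bases),
                      vapply(strsplit(sim$reads$qual, ""), function(ch)
                        paste(rev(ch), collapse = ""), character(1)))
  res2 <- classify_library(flipped, fs)
  expect_equal(res1$calls$category, res2$calls$category)
  expect_equal(as.data.frame(res1$table), as.data.frame(res2$table))
})

test_that("empty input produces an empty table with a warning", {
  loc <- study_locus()
  fs <- derive_features(loc)
  empty <- read_set(character(0), character(0), character(0))
  expect_warning(res <- classify_library(empty, fs), "empty")
  expect_equal(nrow(res$calls), 0L)
  expect_equal(attr(res$table, "total"), 0L)
})

test_that("parameter optimization minimizes control false positives with the stated tie-break", {
  loc <- study_locus()
  # zero-error control: every cell is perfect; tie-break -> largest d, smallest k
  ctrl0 <- simulate_library(loc, sim_config(
    n_reads = 40L, seed = 41L, proportions = c(unedited = 1),
    errors = zero_error_model()))$reads
  opt0 <- optimize_params(ctrl0, loc, k_grid = c(17L, 25L), dist_grid = 0:2)
  expect_true(all(opt0$diagnostics$objective == 0))
  expect_equal(opt0$max_dist, 2L)
  expect_equal(opt0$k, 17L)
  expect_equal(nrow(opt0$diagnostics), 6L)

  # single-cell grid returns that cell
  opt1 <- optimize_params(ctrl0, loc, k_grid = 25L, dist_grid = 2L)
  expect_equal(c(opt1$k, opt1$max_dist), c(25L, 2L))

  expect_error(optimize_params(ctrl0, loc, k_grid = integer(0)), "empty")
})

test_that("control false-positive rate decreases with edit-distance tolerance", {
  loc <- study_locus()
  ctrl <- simulate_library(loc, sim_config(
    n_reads = 250L, seed = 43L, proportions = c(unedited = 1)))$reads
  opt <- optimize_params(ctrl, loc, k_grid = 25L, dist_grid = 0:2)
  d <- opt$diagnostics
  obj <- d$objective[order(d$max_dist)]
  expect_true(all(diff(obj) <= 0))
  expect_equal(opt$max_dist, 2L)
})
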