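test_that("FASTA write/read round-trips random records", {
  recs <- data.frame(id = sprintf("r%03d", 1:50),
                     sequence = random_hexapeptides(50, seed = 9),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("FASTA reader handles basic and degenerate inputs", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "NFGAIL"), path)
  got <- read_fasta(path)
  expect_equal(got$id, "p1")
  expect_equal(got$sequence, "NFGAIL")

  writeLines(character(0), path)
  expect_equal(nrow(read_fasta(path)), 0L)

  writeLines(c("NFGAIL", ">p1"), path)
  expect_error(read_fasta(path), "line 1")

  writeLines(c(">px", "NFGXIL", ">p2", "NFGAIL"), path)
  expect_warning(got <- read_fasta(path), "1 record")
  expect_equal(got$id, "p2")
})

test_that("label tables map labels, catch duplicates and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tlabel",
               "a\tNFGAIL\tAmyloid",
               "b\tSTNQCP\tamyloid",
               "c\tDEKRHS\tnon-amyloid"), path)
  ds <- read_label_table(path)
  cc <- class_counts(ds)
  expect_equal(unname(cc[["amyloid"]]), 2L)
  expect_equal(unname(cc[["non-amyloid"]]), 1L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_label_table(ds, out, format = "csv")
  expect_equal(read_label_table(out), ds)

  writeLines(c("id\tsequence\tlabel", "a\tNFGAIL\tamyloid",
               "a\tSTNQCP\tnon-amyloid"), path)
  expect_error(read_label_table(path), "duplicate id")

  writeLines(c("id\tsequence\tlabel", "a\tNFGAIL\tmaybe"), path)
  expect_error(read_label_table(path), "unknown label")
})

test_that("length filtering matches a brute-force census", {
  withr::with_seed(4, {
    lens <- sample(4:8, 60, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(AA20, l, replace = TRUE), collapse = "")
    }, character(1))
  })
  ds <- peptide_set(sprintf("s%02d", 1:60), seqs,
                    rep(c("amyloid", "non-amyloid"), 30))
  kept <- filter_by_length(ds, 6)
  expect_equal(nrow(kept), sum(nchar(seqs) == 6))
  expect_equal(kept$id, ds$id[nchar(ds$sequence) == 6])  # order preserved
  all6 <- filter_by_length(kept, 6)
  expect_equal(all6, kept)  # identity on uniform-length input
})

test_that("sequence deduplication keeps first occurrence, flags conflicts", {
  ds <- peptide_set(c("a", "b", "c"), c("NFGAIL", "NFGAIL", "STNQCP"),
                    c("amyloid", "amyloid", "non-amyloid"))
  dd <- dedupe_by_sequence(ds)
  expect_equal(dd$id, c("a", "c"))
  bad <- peptide_set(c("a", "b"), c("NFGAIL", "NFGAIL"),
                     c("amyloid", "non-amyloid"))
  expect_error(dedupe_by_sequence(bad), "conflict")
})

test_that("downsampling balances to the minority count deterministically", {
  ds <- peptide_set(sprintf("s%02d", 1:14),
                    random_hexapeptides(14, seed = 2),
                    c(rep("amyloid", 5), rep("non-amyloid", 9)))
  res <- balance_downsample(ds, seed = 7)
  cc <- class_counts(res$balanced)
  expect_equal(unname(cc[["amyloid"]]), 5L)
  expect_equal(unname(cc[["non-amyloid"]]), 5L)
  expect_equal(nrow(res$removed), 4L)
  expect_true(all(res$removed$label == "non-amyloid"))
  res2 <- balance_downsample(ds, seed = 7)
  expect_identical(res$removed$id, res2$removed$id)
  res3 <- balance_downsample(ds, seed = 8)
  expect_false(identical(res$removed$id, res3$removed$id))

  one_class <- peptide_set("x", "NFGAIL", "amyloid")
  expect_error(balance_downsample(one_class), "both classes")
})

test_that("splits have exact per-class sizes and are id-disjoint", {
  ds <- gen_labelled_fixture(fixture_spec(30, seed = 5))
  sp <- split_spec(train_per_class = 20, test_per_class = 5, seed = 1)
  expect_message(split <- make_split(ds, sp), "leftover")
  expect_equal(nrow(split$train), 40L)
  expect_equal(nrow(split$test), 10L)
  expect_equal(unname(class_counts(split$train)[["amyloid"]]), 20L)
  expect_equal(unname(class_counts(split$test)[["non-amyloid"]]), 5L)
  expect_equal(attr(split, "n_discarded"), 10L)

  for (seed in 1:25) {
    s <- suppressMessages(
      make_split(ds, split_spec(20, 5, seed = seed)))
    expect_length(intersect(s$train$id, s$test$id), 0)
  }

  tiny <- gen_labelled_fixture(fixture_spec(2, seed = 6))
  s <- make_split(tiny, split_spec(1, 1, seed = 3))
  expect_equal(nrow(s$train), 2L)
  expect_equal(nrow(s$test), 2L)
  expect_length(intersect(s$train$id, s$test$id), 0)

  expect_error(make_split(tiny, split_spec(5, 2)), "insufficient")
})

test_that("robustness pairs satisfy size, disjointness and distinctness", {
  pool <- gen_labelled_fixture(fixture_spec(40, seed = 11))
  sp <- split_spec(train_per_class = 25, test_per_class = 5, seed = 1)
  pairs <- make_robustness_pairs(pool, n_pairs = 8, spec = sp, seed = 42)
  expect_length(pairs, 8)
  keys <- vapply(pairs, function(p) {
    paste(sort(c(p$train$id, p$test$id)), collapse = ",")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (p in pairs) {
    expect_equal(nrow(p$train), 50L)
    expect_equal(nrow(p$test), 10L)
    expect_equal(unname(class_counts(p$train)[["amyloid"]]), 25L)
    expect_length(intersect(p$train$id, p$test$id), 0)
  }
  pairs2 <- make_robustness_pairs(pool, n_pairs = 8, spec = sp, seed = 42)
  expect_identical(pairs, pairs2)
})

test_that("split manifests record every partitioned record", {
  ds <- gen_labelled_fixture(fixture_spec(10, seed = 8))
  split <- suppressMessages(make_split(ds, split_spec(6, 2, seed = 1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(split, path)
  man <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(sort(unique(man$partition)), c("test", "train"))
  expect_equal(sum(man$partition == "train"), 12L)
  expect_setequal(man$id[man$partition == "test"], split$test$id)
})
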