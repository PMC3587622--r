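small_cons <- design_constraints(length = 18, count = 10, min_distance = 4,
                                 padding = 0, seed = 91)

test_that("random candidates respect the GC bounds and the seed", {
  cons <- design_constraints(length = 18, count = 1)
  withr::with_seed(17, draws <- replicate(2000, random_candidate(cons)))
  gcs <- gc_content(draws)
  expect_true(all(gcs >= cons$gc_min & gcs <= cons$gc_max))
  expect_true(all(nchar(draws) == 18))
  withr::with_seed(3, d1 <- random_candidate(cons))
  withr::with_seed(3, d2 <- random_candidate(cons))
  expect_identical(d1, d2)
  # degenerate GC window: only G/C sequences
  pure <- design_constraints(length = 4, count = 1, gc_min = 1, gc_max = 1,
                             min_distance = 1)
  withr::with_seed(8, s <- random_candidate(pure))
  expect_true(grepl("^[GC]+$", s))
})

test_that("try_insert enforces the minimum padded distance", {
  set <- generate_barcodes(small_cons)
  empty <- set
  empty$barcodes <- character(0)
  first <- try_insert(empty, set$barcodes[1])
  expect_true(first$accepted)                       # vacuous minimum
  dup <- try_insert(set, set$barcodes[3])
  expect_false(dup$accepted)                        # distance 0 to itself
  # candidate at exactly d_min from its nearest accepted barcode
  b <- set$barcodes[1]
  cand <- b
  positions <- c(2, 6, 10, 14)
  for (p in positions) {
    old <- substr(cand, p, p)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(cand, p, p) <- new
  }
  d_all <- padded_distance(rep(cand, length(set$barcodes)), set$barcodes, 0)
  if (min(d_all) == set$min_distance) {
    expect_true(try_insert(set, cand)$accepted)
  }
})

test_that("generated sets satisfy both set-level invariants", {
  set <- generate_barcodes(small_cons)
  expect_length(set$barcodes, 10)
  expect_false(any(duplicated(set$barcodes)))
  expect_true(all(nchar(set$barcodes) == 18))
  audit <- audit_barcode_set(set)
  expect_gte(audit$min_pairwise_distance, set$min_distance)
  expect_true(audit$all_pass_filters)
  expect_equal(sum(audit$histogram$pair_count), 10 * 9 / 2)
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- generate_barcodes(small_cons)
  s2 <- generate_barcodes(small_cons)
  expect_identical(s1$barcodes, s2$barcodes)
  expect_identical(s1$report, s2$report)
  s3 <- generate_barcodes(small_cons, seed = 92)
  expect_false(identical(s1$barcodes, s3$barcodes))
})

test_that("impossible constraints exhaust attempts with a report, not a hang", {
  cons <- design_constraints(length = 4, count = 2, min_distance = 5,
                             gc_min = 0, gc_max = 1, seed = 1)
  set <- generate_barcodes(cons, max_attempts = 150)
  expect_false(set$report$completed)
  expect_lt(length(set$barcodes), 2)
  expect_equal(set$report$attempts, 150)
})

test_that("recommended_min_distance implements the 2e + 1 rule", {
  expect_equal(recommended_min_distance(0), 1L)
  expect_equal(recommended_min_distance(1), 3L)
  expect_equal(recommended_min_distance(2), 5L)
  expect_error(recommended_min_distance(-1), ">= 0")
})

test_that("barcode and histogram files round-trip", {
  set <- generate_barcodes(small_cons)
  bc_path <- withr::local_tempfile(fileext = ".txt")
  write_barcodes(set, bc_path)
  expect_identical(read_barcodes(bc_path), set$barcodes)
  expect_equal(length(readLines(bc_path)), length(set$barcodes))

  hist <- distance_histogram(set)
  expect_true(all(hist$distance >= set$min_distance))  # no mass below d_min
  h_path <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(hist, h_path)
  back <- read.table(h_path, sep = "\t", col.names = c("distance", "pair_count"))
  expect_equal(back$distance, hist$distance)
  expect_equal(back$pair_count, hist$pair_count)

  empty_path <- withr::local_tempfile(fileext = ".txt")
  write_barcodes(character(0), empty_path)
  expect_length(read_barcodes(empty_path), 0)
})

test_that("tidy, glance and autoplot summarise a set", {
  set <- generate_barcodes(small_cons)
  td <- tidy(set)
  expect_equal(nrow(td), 10)
  expect_true(all(td$gc >= 0.45 & td$gc <= 0.65))
  gl <- glance(set)
  expect_equal(gl$n_barcodes, 10)
  expect_true(gl$completed)
  p <- autoplot(set)
  expect_s3_class(p, "ggplot")
})
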