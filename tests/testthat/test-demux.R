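make_set <- function(bcs, d_min = 4L, P = 0L) {
  cons <- design_constraints(length = nchar(bcs[1]), count = length(bcs),
                             min_distance = d_min, padding = P)
  structure(list(barcodes = bcs, length = cons$length, min_distance = d_min,
                 padding = P, constraints = cons,
                 report = list(attempts = length(bcs),
                               filter_failures = integer(0),
                               distance_rejections = 0L, completed = TRUE)),
            class = "barcode_set")
}

test_that("extract_window implements the clipped half-open interval", {
  p0 <- demux_params(barcode_start = 0, positional_error = 0)
  r <- paste(rep("A", 50), collapse = "")
  expect_equal(extract_window(r, p0, 18),
               list(window = strrep("A", 18), start = 0L))
  p1 <- demux_params(barcode_start = 5, positional_error = 1)
  w <- extract_window(paste0(strrep("C", 4), strrep("G", 46)), p1, 18)
  expect_equal(w$start, 4L)
  expect_equal(nchar(w$window), 20)         # bases [4, 24)
  pm <- demux_params(positional_error = -1)
  expect_equal(extract_window("ACGTACGT", pm, 18)$window, "ACGTACGT")
  # start beyond the read end: empty window, classified unmatched
  pfar <- demux_params(barcode_start = 30)
  expect_equal(extract_window("ACGT", pfar, 18)$window, "")
})

test_that("verbatim and one-error reads are matched to the right barcode", {
  set <- generate_barcodes(design_constraints(length = 18, count = 50,
                                              min_distance = 4, seed = 131))
  idx <- build_kmer_index(set, 6)
  withr::with_seed(14, tail <- rand_dna(1, 30))
  read <- list(read_id = "r1",
               sequence = paste0(set$barcodes[7], tail),
               quality = strrep("I", 48))
  res <- classify_read(read, idx, set, demux_params(k = 6))
  expect_equal(res$status, "matched")
  expect_equal(res$barcode_id, 7L)
  expect_equal(res$distance, 0L)
  expect_equal(res$offset, 0L)

  # every single-base substitution of every barcode comes back correctly
  reads <- list()
  truth <- integer(0)
  for (i in seq_along(set$barcodes)) {
    for (p in 1:18) {
      s <- set$barcodes[i]
      old <- substr(s, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), old)) {
        substr(s, p, p) <- b
        reads[[length(reads) + 1L]] <- s
        truth <- c(truth, i)
      }
    }
  }
  tbl <- tibble::tibble(read_id = as.character(seq_along(reads)),
                        sequence = unlist(reads),
                        quality = strrep("?", 18))
  out <- demultiplex(tbl, set, demux_params(k = 6))
  expect_true(all(out$status == "matched"))
  expect_equal(out$barcode_id, truth)
  expect_true(all(out$distance == 1L))
})

test_that("equidistant reads are ambiguous, never falsely matched", {
  b1 <- "AAAACCCCGGGGTTTTAA"
  b2 <- b1
  for (p in c(1, 5, 9, 13)) {
    substr(b2, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(b2, p, p)]
  }
  expect_equal(levenshtein(b1, b2), 4L)
  mid <- b1
  for (p in c(1, 5)) substr(mid, p, p) <- substr(b2, p, p)
  expect_equal(levenshtein(mid, b1), 2L)
  expect_equal(levenshtein(mid, b2), 2L)
  set <- make_set(c(b1, b2))
  read <- list(read_id = "amb", sequence = mid, quality = strrep("?", 18))
  res <- classify_read(read, NULL, set, demux_params(max_distance = 2))
  expect_equal(res$status, "ambiguous")
  out <- demultiplex(tibble::tibble(read_id = "amb", sequence = mid,
                                    quality = strrep("?", 18)),
                     set, demux_params(k = 6, max_distance = 2))
  expect_equal(out$status, "ambiguous")
})

test_that("quality tie-breaking prefers mismatches on low-confidence bases", {
  tied <- list(list(barcode_id = 1L, mismatch_positions = c(0L, 4L)),
               list(barcode_id = 2L, mismatch_positions = c(1L, 5L)))
  q <- paste0("#", "I", "I", "I", "#", "I")   # Q2 at 0 and 4, Q40 elsewhere
  expect_equal(quality_tie_break(tied, q), 1L)
  expect_true(is.na(quality_tie_break(tied, strrep("I", 6))))
  three <- list(list(barcode_id = 1L, mismatch_positions = 0L),
                list(barcode_id = 2L, mismatch_positions = 1L),
                list(barcode_id = 3L, mismatch_positions = 2L))
  qq <- paste0("+", "+", "?")  # sums 10, 10, 30: still tied
  expect_true(is.na(quality_tie_break(three, qq)))

  # end-to-end: the candidate whose mismatch sits on the shaky base wins
  b1 <- "AAAACCCCGGGGTTTTAA"
  b2 <- b1; substr(b2, 2, 2) <- "G"
  b3 <- b1; substr(b3, 9, 9) <- "A"
  set <- make_set(c(b2, b3), d_min = 1L)
  q <- strrep("I", 18); substr(q, 2, 2) <- "#"  # base 2 is low quality
  out <- demultiplex(tibble::tibble(read_id = "t", sequence = b1, quality = q),
                     set, demux_params(k = 6, max_distance = 2))
  expect_equal(out$status, "matched")
  expect_equal(out$barcode_id, 1L)   # b2's mismatch lies on the Q2 base
})

test_that("batch classification agrees with the single-read reference path", {
  set <- generate_barcodes(design_constraints(length = 14, count = 30,
                                              min_distance = 4, padding = 1,
                                              seed = 17))
  sim <- simulate_reads(set, 150, split_error_model(0.1), seed = 21)
  params <- demux_params(positional_error = 1, k = 4, max_distance = 2,
                         padding = 1)
  batch <- demultiplex(sim, set, params)
  idx <- build_kmer_index(set, 4)
  for (i in seq_len(nrow(sim$reads))) {
    single <- classify_read(as.list(sim$reads[i, ]), idx, set, params)
    expect_equal(batch$status[i], single$status)
    expect_equal(batch$barcode_id[i], single$barcode_id)
    expect_equal(batch$distance[i], single$distance)
  }
})

test_that("index retrieval matches exhaustive candidates under q-gram recall", {
  set <- generate_barcodes(design_constraints(length = 18, count = 40,
                                              min_distance = 5, seed = 19))
  sim <- simulate_reads(set, 120, error_model(0.03), seed = 23)
  params <- demux_params(k = recommended_k(18, 2), max_distance = 2)
  idx <- build_kmer_index(set, params$k)
  for (i in seq_len(nrow(sim$reads))) {
    read <- as.list(sim$reads[i, ])
    n_err <- levenshtein(read$sequence, set$barcodes[sim$truth$barcode_id[i]])
    if (n_err > 2) next  # recall only guaranteed for <= 2 substitutions
    with_idx <- classify_read(read, idx, set, params)
    exhaustive <- classify_read(read, NULL, set, params)
    expect_equal(with_idx$status, exhaustive$status)
    expect_equal(with_idx$barcode_id, exhaustive$barcode_id)
  }
})

test_that("per-read results are independent of processing order", {
  set <- generate_barcodes(design_constraints(length = 12, count = 20,
                                              min_distance = 3, seed = 29))
  sim <- simulate_reads(set, 80, error_model(0.05), seed = 31)
  params <- demux_params(k = 4, max_distance = 1)
  fwd <- demultiplex(sim, set, params)
  perm <- withr::with_seed(1, sample(nrow(sim$reads)))
  shuffled <- demultiplex(sim$reads[perm, ], set, params)
  restored <- shuffled[order(perm), ]
  expect_equal(restored$status, fwd$status)
  expect_equal(restored$barcode_id, fwd$barcode_id)
})

test_that("FASTQ demultiplexing writes annotated status streams", {
  dir <- withr::local_tempdir()
  set <- generate_barcodes(design_constraints(length = 12, count = 10,
                                              min_distance = 3, seed = 41))
  sim <- simulate_reads(set, 40, error_model(0), seed = 43)
  fq <- file.path(dir, "in.fastq")
  write_fastq(sim$reads, fq)
  bcf <- file.path(dir, "barcodes.txt")
  write_barcodes(set, bcf)
  summary <- demultiplex_fastq(fq, bcf, demux_params(k = 4, max_distance = 1),
                               out_prefix = file.path(dir, "out"),
                               write_results = TRUE)
  expect_equal(summary$n[summary$status == "matched"], 40L)
  expect_equal(sum(summary$n), 40L)
  matched <- readLines(file.path(dir, "out.matched.fastq"))
  expect_length(matched, 160)
  plus <- matched[seq(3, length(matched), by = 4)]
  expect_true(all(grepl("^\\+BC:[ACGT]{12} ID:\\d+ ED:0$", plus)))
  # annotation carries the true barcode sequence
  ids <- as.integer(sub(".*ID:(\\d+) .*", "\\1", plus))
  bcs_in_plus <- sub("^\\+BC:([ACGT]+) .*", "\\1", plus)
  expect_equal(bcs_in_plus, set$barcodes[ids])
  # the per-read results table round-trips into the evaluator
  tab <- utils::read.table(file.path(dir, "out.results.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 40)
  expect_equal(evaluate_demux(tab, sim)$pct_correct, 100)
  expect_s3_class(autoplot(summary), "ggplot")
})

test_that("paired-end mates inherit the read-1 assignment", {
  dir <- withr::local_tempdir()
  set <- generate_barcodes(design_constraints(length = 12, count = 5,
                                              min_distance = 3, seed = 47))
  sim <- simulate_reads(set, 12, error_model(0), seed = 49)
  mates <- sim$reads
  withr::with_seed(51, mates$sequence <- rand_dna(12, 12))
  fq1 <- file.path(dir, "r1.fastq"); write_fastq(sim$reads, fq1)
  fq2 <- file.path(dir, "r2.fastq"); write_fastq(mates, fq2)
  demultiplex_fastq(fq1, set, demux_params(k = 4, max_distance = 1),
                    out_prefix = file.path(dir, "pe"), fastq2 = fq2)
  m1 <- readLines(file.path(dir, "pe.matched.fastq"))
  m2 <- readLines(file.path(dir, "pe.matched.R2.fastq"))
  expect_length(m2, length(m1))
  # same annotation on both mates, mate sequences from the R2 file
  expect_equal(m1[seq(3, length(m1), 4)], m2[seq(3, length(m2), 4)])
  expect_equal(m2[seq(2, length(m2), 4)], mates$sequence)
})

test_that("degenerate inputs are handled without crashing", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fastq")
  writeLines(character(0), empty)
  set <- make_set(c("ACGTACGTACGT", "TTTTCCCCAAAA"), d_min = 3L)
  s <- demultiplex_fastq(empty, set, demux_params(k = 4, max_distance = 1),
                         out_prefix = file.path(dir, "e"))
  expect_equal(sum(s$n), 0L)
  expect_true(file.exists(file.path(dir, "e.matched.fastq")))
  # malformed FASTQ names the offending structure
  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(read_fastq(bad), "multiple of 4")
  bad2 <- file.path(dir, "bad2.fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad2)
  expect_error(read_fastq(bad2), "record 1")
  # all-N read and barcode start beyond the read end are unmatched
  out <- demultiplex(tibble::tibble(read_id = c("n", "short"),
                                    sequence = c(strrep("N", 12), "ACG"),
                                    quality = c(strrep("I", 12), "III")),
                     set, demux_params(k = 4, max_distance = 1))
  expect_equal(out$status, c("unmatched", "unmatched"))
})
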