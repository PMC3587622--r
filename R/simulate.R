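#' Sequencing error model
#'
#' Independent per-base error probabilities. In `"substitutions"` mode the
#' indel rates are forced to zero; `"all"` mode allows all three edit types.
#'
#' @param substitution,insertion,deletion Per-base event probabilities in
#'   `[0, 1]`. A substitution replaces the base with a uniformly chosen
#'   different base; an insertion adds a uniform base after the position; a
#'   deletion removes the base.
#' @param mode `"substitutions"` or `"all"`.
#' @return An `error_model` object.
#' @examples
#' error_model(0.02)                       # 2% substitution-only errors
#' split_error_model(0.02)                 # 2% total, 80/10/10 sub/ins/del
#' @export
error_model <- function(substitution = 0.02, insertion = 0, deletion = 0,
                        mode = c("substitutions", "all")) {
  mode <- match.arg(mode)
  if (mode == "substitutions") {
    insertion <- 0
    deletion <- 0
  }
  rates <- c(substitution, insertion, deletion)
  if (any(rates < 0 | rates > 1)) .stopf("error rates must be in [0, 1]")
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion, mode = mode), class = "error_model")
}

#' @describeIn error_model Split a total per-base error rate 80/10/10 among
#'   substitutions, insertions and deletions (all-edits mode).
#' @param total Total per-base error probability.
#' @export
split_error_model <- function(total = 0.02) {
  error_model(substitution = 0.8 * total, insertion = 0.1 * total,
              deletion = 0.1 * total, mode = "all")
}

.rand_bases <- function(n) sample(BASES, n, replace = TRUE)

# substitute each TRUE position with a uniformly chosen different base
.substitute <- function(chars, mask) {
  k <- sum(mask)
  if (k == 0L) return(chars)
  idx <- match(chars[mask], BASES)
  chars[mask] <- BASES[((idx - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
  chars
}

#' Simulate barcoded reads with ground truth
#'
#' Each read picks a barcode uniformly at random, places it at
#' `barcode_start`, fills the flanks with uniform random bases, and then
#' applies the error model base by base: each template base is deleted with
#' probability `deletion`, otherwise substituted with probability
#' `substitution`; independently, a uniform base is inserted after it with
#' probability `insertion`. Qualities are constant Q30. Given the same seed,
#' the output is byte-identical.
#'
#' @param set A `barcode_set` or character vector of barcodes.
#' @param n Number of reads.
#' @param em An [error_model()].
#' @param read_length Read length before errors; defaults to the barcode
#'   length (bare barcoded reads). Must be at least
#'   `barcode_start + barcode length`.
#' @param barcode_start 0-based position of the barcode within the read.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A `simulated_reads` object: `$reads` is a tibble
#'   (`read_id`, `sequence`, `quality`, `barcode_id`), `$truth` the
#'   `read_id` to `barcode_id` map.
#' @export
simulate_reads <- function(set, n, em = error_model(),
                           read_length = NULL, barcode_start = 0L,
                           seed = NULL) {
  bcs <- .bc_chr(set)
  L <- unique(nchar(bcs))
  if (length(L) != 1L) .stopf("barcodes must have equal length")
  barcode_start <- as.integer(barcode_start)
  if (is.null(read_length)) read_length <- barcode_start + L
  read_length <- as.integer(read_length)
  if (read_length < barcode_start + L) {
    .stopf("read_length (%d) must be at least barcode_start + L (%d)",
           read_length, barcode_start + L)
  }
  run <- function() {
    ids <- sample.int(length(bcs), n, replace = TRUE)
    tail_len <- read_length - barcode_start - L
    templates <- bcs[ids]
    if (barcode_start > 0L || tail_len > 0L) {
      pre <- vapply(seq_len(n), function(i)
        paste(.rand_bases(barcode_start), collapse = ""), character(1))
      post <- vapply(seq_len(n), function(i)
        paste(.rand_bases(tail_len), collapse = ""), character(1))
      templates <- paste0(pre, templates, post)
    }
    m <- matrix(unlist(strsplit(templates, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
    sub_mask <- matrix(runif(n * read_length) < em$substitution, n, read_length)
    m[] <- .substitute(as.vector(m), as.vector(sub_mask))
    if (em$insertion > 0 || em$deletion > 0) {
      del_mask <- matrix(runif(n * read_length) < em$deletion, n, read_length)
      ins_mask <- matrix(runif(n * read_length) < em$insertion, n, read_length)
      touched <- which(rowSums(del_mask) + rowSums(ins_mask) > 0)
      seqs <- character(n)
      plain <- setdiff(seq_len(n), touched)
      if (length(plain)) {
        seqs[plain] <- apply(m[plain, , drop = FALSE], 1L, paste, collapse = "")
      }
      for (r in touched) {
        out <- character(0)
        for (i in seq_len(read_length)) {
          if (!del_mask[r, i]) out <- c(out, m[r, i])
          if (ins_mask[r, i]) out <- c(out, .rand_bases(1L))
        }
        seqs[r] <- paste(out, collapse = "")
      }
    } else {
      seqs <- apply(m, 1L, paste, collapse = "")
    }
    tibble(
      read_id = sprintf("read%07d", seq_len(n)),
      sequence = seqs,
      quality = strrep("?", nchar(seqs)),  # constant Q30 (Phred+33)
      barcode_id = ids
    )
  }
  reads <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  structure(list(reads = reads,
                 truth = reads[, c("read_id", "barcode_id")]),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("<simulated_reads> %d read(s) over %d barcode(s)\n",
              nrow(x$reads), length(unique(x$truth$barcode_id))))
  invisible(x)
}

#' Evaluate demultiplexing results against simulation truth
#'
#' A read is wrongly classified when it is matched to a barcode different
#' from its truth label. Reads that cannot be uniquely classified comprise
#' the ambiguous reads (distance ties that survive the quality tie-break)
#' and the unmatched reads (no candidate within the distance cut-off).
#'
#' @param results A tibble as returned by [demultiplex()].
#' @param truth A `simulated_reads` object or a tibble with `read_id`,
#'   `barcode_id`.
#' @return A one-row tibble: `n_reads`, `n_correct`, `n_wrong`,
#'   `n_ambiguous`, `n_unmatched` and the corresponding percentages,
#'   including `pct_not_unique` (ambiguous + unmatched).
#' @export
evaluate_demux <- function(results, truth) {
  if (inherits(truth, "simulated_reads")) truth <- truth$truth
  j <- match(results$read_id, truth$read_id)
  if (anyNA(j)) {
    .stopf("read identifier '%s' is missing from the truth table",
           results$read_id[which(is.na(j))[1]])
  }
  expected <- truth$barcode_id[j]
  n <- nrow(results)
  matched <- results$status == "matched"
  n_wrong <- sum(matched & results$barcode_id != expected)
  n_correct <- sum(matched & results$barcode_id == expected)
  n_amb <- sum(results$status == "ambiguous")
  n_unm <- sum(results$status == "unmatched")
  pct <- function(x) if (n == 0L) 0 else 100 * x / n
  tibble(
    n_reads = n, n_correct = n_correct, n_wrong = n_wrong,
    n_ambiguous = n_amb, n_unmatched = n_unm,
    pct_correct = pct(n_correct), pct_wrong = pct(n_wrong),
    pct_ambiguous = pct(n_amb), pct_unmatched = pct(n_unm),
    pct_not_unique = pct(n_amb + n_unm)
  )
}
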