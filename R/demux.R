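#' Demultiplexing parameters
#'
#' @param barcode_start 0-based position of the barcode within the read.
#' @param positional_error Allowed deviation of the barcode start (bases);
#'   `-1` means the position is unknown and the whole read is scanned (slower
#'   and less accurate).
#' @param k K-mer length of the candidate index; default
#'   `recommended_k(L, max_distance)` resolved against the barcode set.
#' @param max_distance Maximum accepted edit distance; default
#'   `floor(d_min / 2)`, which makes the design guarantee operational: with
#'   `d_min >= 2e + 1`, reads carrying up to `e` edits are always uniquely
#'   classified. When the barcodes come from a plain list without design
#'   metadata, the default assumes `d_min = 4` (i.e. `max_distance = 2`).
#' @param padding Wildcard padding applied to the barcode during alignment;
#'   should mirror the padding used at design time.
#' @return A `demux_params` object.
#' @export
demux_params <- function(barcode_start = 0L, positional_error = 0L,
                         k = NULL, max_distance = NULL, padding = 0L) {
  positional_error <- as.integer(positional_error)
  if (positional_error < -1L) .stopf("positional_error must be >= -1")
  if (!is.null(max_distance) && max_distance < 0L) .stopf("max_distance must be >= 0")
  structure(list(
    barcode_start = as.integer(barcode_start),
    positional_error = positional_error,
    k = if (is.null(k)) NULL else as.integer(k),
    max_distance = if (is.null(max_distance)) NULL else as.integer(max_distance),
    padding = as.integer(padding)
  ), class = "demux_params")
}

#' @export
print.demux_params <- function(x, ...) {
  cat(sprintf("<demux_params> start = %d, positional_error = %d, k = %s, max_distance = %s, padding = %d\n",
              x$barcode_start, x$positional_error,
              if (is.null(x$k)) "auto" else x$k,
              if (is.null(x$max_distance)) "auto" else x$max_distance,
              x$padding))
  invisible(x)
}

.resolve_params <- function(params, set) {
  L <- unique(nchar(.bc_chr(set)))
  if (length(L) != 1L) .stopf("barcodes must have equal length")
  d_min <- if (inherits(set, "barcode_set")) set$min_distance else 4L
  if (is.null(params$max_distance)) params$max_distance <- d_min %/% 2L
  if (is.null(params$k)) params$k <- recommended_k(L, params$max_distance)
  params$L <- L
  params
}

#' Extract the putative barcode window from a read
#'
#' The half-open window `[max(0, start - pe), min(len, start + L + pe))`,
#' clipped at the read bounds; the whole read when `positional_error = -1`.
#'
#' @param sequence The read sequence.
#' @param params A [demux_params()] object.
#' @param L Barcode length.
#' @return A list with `window` (possibly empty) and `start` (0-based window
#'   start within the read).
#' @export
extract_window <- function(sequence, params, L) {
  stopifnot(length(sequence) == 1L)
  len <- nchar(sequence)
  pe <- params$positional_error
  if (pe < 0L) {
    return(list(window = sequence, start = 0L))
  }
  ws <- max(0L, params$barcode_start - pe)
  we <- min(len, params$barcode_start + L + pe)
  if (we <= ws) return(list(window = "", start = ws))
  list(window = substr(sequence, ws + 1L, we), start = ws)
}

#' Quality-aware tie-breaking between equally distant barcodes
#'
#' For each tied candidate, the Phred scores of the read positions at its
#' alignment's edit columns are summed; the candidate with the lowest sum
#' wins, because its mismatches sit on the least trustworthy bases and are
#' therefore the most plausible sequencing errors. Equal sums leave the read
#' ambiguous.
#'
#' @param tied A list of candidates, each a list with `barcode_id` and
#'   `mismatch_positions` (0-based read positions of the edit columns).
#' @param quality The read's quality string (Sanger Phred+33).
#' @return The winning `barcode_id`, or `NA` if still tied.
#' @export
quality_tie_break <- function(tied, quality) {
  if (length(tied) < 2L) .stopf("quality_tie_break needs at least 2 tied candidates")
  phred <- as.integer(charToRaw(quality)) - 33L
  sums <- vapply(tied, function(t) {
    pos <- t$mismatch_positions + 1L
    pos <- pos[pos >= 1L & pos <= length(phred)]
    sum(phred[pos])
  }, numeric(1))
  winners <- which(sums == min(sums))
  if (length(winners) == 1L) tied[[winners]]$barcode_id else NA_integer_
}

#' Classify a single read against a barcode set
#'
#' Reference implementation of the per-read pipeline: window extraction,
#' k-mer candidate retrieval, semi-global alignment of each candidate, and
#' status assignment with quality tie-breaking. [demultiplex()] runs the
#' same logic in compiled code; the two are equivalent read by read.
#'
#' @param read A list (or one-row tibble) with `sequence` and optionally
#'   `quality` and `read_id`.
#' @param index A `kmer_index` built over `set` with the same `k`, or `NULL`
#'   to align against every barcode (exhaustive candidates).
#' @param set A `barcode_set` or character vector of barcodes.
#' @param params A [demux_params()] object.
#' @return A one-row tibble: `read_id`, `status` (`"matched"`, `"ambiguous"`
#'   or `"unmatched"`), `barcode_id`, `distance`, `offset`.
#' @export
classify_read <- function(read, index, set, params = demux_params()) {
  params <- .resolve_params(params, set)
  bcs <- .bc_chr(set)
  if (!is.null(index) && index$k != params$k) {
    .stopf("index was built with k = %d but params request k = %d",
           index$k, params$k)
  }
  read_id <- if (!is.null(read$read_id)) read$read_id else NA_character_
  res <- function(status, id = NA_integer_, d = NA_integer_, off = NA_integer_) {
    tibble(read_id = read_id, status = status, barcode_id = id,
           distance = d, offset = off)
  }
  win <- extract_window(read$sequence, params, params$L)
  if (!nzchar(win$window)) return(res("unmatched"))
  cands <- if (is.null(index)) seq_along(bcs) else query_candidates(win$window, index)
  if (length(cands) == 0L) return(res("unmatched"))
  alns <- lapply(cands, function(i) {
    semi_global_align(bcs[i], win$window, params$padding)
  })
  dists <- vapply(alns, `[[`, integer(1), "distance")
  best <- min(dists)
  if (best > params$max_distance) return(res("unmatched"))
  ties <- which(dists == best)
  pick <- ties[1]
  if (length(ties) > 1L) {
    winner <- NA_integer_
    if (!is.null(read$quality) && nzchar(read$quality)) {
      tied <- lapply(ties, function(t) {
        list(barcode_id = cands[t],
             mismatch_positions = alns[[t]]$mismatch_positions + win$start)
      })
      winner <- quality_tie_break(tied, read$quality)
    }
    if (is.na(winner)) return(res("ambiguous", d = best))
    pick <- ties[which(cands[ties] == winner)]
  }
  res("matched", id = cands[pick], d = best,
      off = win$start + alns[[pick]]$offset)
}

.status_labels <- c("matched", "ambiguous", "unmatched")

#' Demultiplex a table of reads
#'
#' Assigns every read to a barcode (or declares it ambiguous/unmatched)
#' using the k-mer candidate index and semi-global alignment, in compiled
#' code. Per-read results are independent of processing order; output rows
#' are in input order.
#'
#' @param reads A tibble with `read_id`, `sequence` and optionally `quality`
#'   (as produced by [read_fastq()] or [simulate_reads()]), or a
#'   `simulated_reads` object.
#' @param set A `barcode_set` or character vector of barcodes.
#' @param params A [demux_params()] object.
#' @return A tibble with `read_id`, `status`, `barcode_id`, `distance`,
#'   `offset` (0-based alignment start of the barcode within the read).
#' @examples
#' set <- generate_barcodes(design_constraints(length = 12, count = 20,
#'                                             min_distance = 3, seed = 7))
#' reads <- tibble::tibble(read_id = "r1", sequence = set$barcodes[1],
#'                         quality = strrep("I", 12))
#' demultiplex(reads, set, demux_params(max_distance = 1))
#' @export
demultiplex <- function(reads, set, params = demux_params()) {
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  params <- .resolve_params(params, set)
  bcs <- .bc_chr(set)
  quals <- if (!is.null(reads$quality)) as.character(reads$quality) else character(0)
  raw <- classify_batch_cpp(as.character(reads$sequence), quals, bcs,
                            params$k, params$barcode_start,
                            params$positional_error, params$max_distance,
                            params$padding)
  tibble(
    read_id = reads$read_id,
    status = .status_labels[raw$status],
    barcode_id = raw$barcode_id,
    distance = raw$distance,
    offset = raw$offset
  )
}

#' Demultiplex FASTQ files
#'
#' Reads single- or paired-end FASTQ, classifies every read-1 barcode, and
#' writes one FASTQ stream per status (`<prefix>.matched.fastq`,
#' `<prefix>.ambiguous.fastq`, `<prefix>.unmatched.fastq`; paired mates go
#' to `<prefix>.matched.R2.fastq` etc.). Matched records carry the best hit
#' on the separator line as `+BC:<sequence> ID:<id> ED:<distance>`; for
#' paired-end input the barcode is located on read 1 and the mate inherits
#' its assignment. Output preserves input order.
#'
#' @param fastq1 Path to the (read-1) FASTQ file.
#' @param barcodes Path to a barcode list (one per line), a character
#'   vector, or a `barcode_set`.
#' @param params A [demux_params()] object.
#' @param out_prefix Output path prefix.
#' @param fastq2 Optional mate FASTQ path (must have the same record count).
#' @param write_results Also write the per-read classification table to
#'   `<prefix>.results.tsv` (columns `read_id`, `status`, `barcode_id`,
#'   `distance`, `offset`), ready for [evaluate_demux()].
#' @return A `demux_summary` tibble of per-status read counts.
#' @export
demultiplex_fastq <- function(fastq1, barcodes, params = demux_params(),
                              out_prefix = "demux", fastq2 = NULL,
                              write_results = FALSE) {
  set <- if (is.character(barcodes) && length(barcodes) == 1L && file.exists(barcodes)) {
    read_barcodes(barcodes)
  } else barcodes
  reads1 <- read_fastq(fastq1)
  reads2 <- NULL
  if (!is.null(fastq2)) {
    reads2 <- read_fastq(fastq2)
    if (nrow(reads2) != nrow(reads1)) {
      .stopf("paired FASTQ record counts differ (%d vs %d)",
             nrow(reads1), nrow(reads2))
    }
  }
  res <- demultiplex(reads1, set, params)
  bcs <- .bc_chr(set)
  plus <- rep("+", nrow(res))
  m <- res$status == "matched"
  plus[m] <- sprintf("+BC:%s ID:%d ED:%d",
                     bcs[res$barcode_id[m]], res$barcode_id[m], res$distance[m])
  for (st in .status_labels) {
    keep <- res$status == st
    write_fastq(reads1[keep, , drop = FALSE],
                sprintf("%s.%s.fastq", out_prefix, st), plus[keep])
    if (!is.null(reads2)) {
      write_fastq(reads2[keep, , drop = FALSE],
                  sprintf("%s.%s.R2.fastq", out_prefix, st), plus[keep])
    }
  }
  if (write_results) {
    utils::write.table(res, sprintf("%s.results.tsv", out_prefix),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts <- vapply(.status_labels, function(st) sum(res$status == st), integer(1))
  out <- tibble(status = .status_labels, n = unname(counts))
  class(out) <- c("demux_summary", class(out))
  out
}

#' @describeIn demultiplex_fastq Bar chart of per-status read counts.
#' @param object A `demux_summary`.
#' @param ... Unused.
#' @method autoplot demux_summary
#' @export
autoplot.demux_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads") +
    ggplot2::theme_minimal()
}
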