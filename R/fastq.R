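#' Read a FASTQ file
#'
#' Minimal 4-line-record FASTQ reader that keeps the quality string verbatim
#' (Sanger Phred+33 encoding is assumed downstream).
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    .stopf("malformed FASTQ '%s': %d line(s) is not a multiple of 4",
           path, length(lines))
  }
  idx <- seq(1L, length(lines), by = 4L)
  heads <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) .stopf("malformed FASTQ record %d: header does not start with '@'", bad[1])
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    .stopf("malformed FASTQ record %d: sequence and quality lengths differ", bad[1])
  }
  tibble(read_id = sub("^@", "", heads), sequence = seqs, quality = quals)
}

#' Write a FASTQ file
#'
#' @param reads A tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @param plus_line Optional character vector of separator lines (one per
#'   read, each starting with `+`); defaults to a bare `+`. The
#'   demultiplexer uses this line to annotate the best-hit barcode.
#' @export
write_fastq <- function(reads, path, plus_line = NULL) {
  n <- nrow(reads)
  if (is.null(plus_line)) plus_line <- rep("+", n)
  stopifnot(length(plus_line) == n)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(4L * n)
  out[seq(1L, 4L * n, 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, 4L * n, 4L)] <- reads$sequence
  out[seq(3L, 4L * n, 4L)] <- plus_line
  out[seq(4L, 4L * n, 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}
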