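.kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  kms <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  kms[!grepl("N", kms, fixed = TRUE)]
}

#' Build a k-mer index over a barcode set
#'
#' Maps every overlapping k-mer of every barcode to the identifiers of the
#' barcodes containing it. Querying a read window with its own k-mers then
#' retrieves a small candidate set instead of the whole barcode list
#' (q-gram filtering). K-mers containing `N` are never indexed.
#'
#' @param set A `barcode_set` or character vector of barcodes.
#' @param k K-mer length, between 1 and the barcode length.
#' @return A `kmer_index` object.
#' @examples
#' idx <- build_kmer_index("ACGT", k = 2)
#' query_candidates("ACGT", idx)
#' @export
build_kmer_index <- function(set, k) {
  bcs <- .bc_chr(set)
  k <- as.integer(k)
  L <- unique(nchar(bcs))
  if (length(L) != 1L) .stopf("barcodes must have equal length")
  if (k < 1L || k > L) .stopf("k must be between 1 and the barcode length (%d)", L)
  per_bc <- lapply(bcs, function(b) unique(.kmers_of(b, k)))
  ids <- rep.int(seq_along(bcs), lengths(per_bc))
  map <- split(ids, unlist(per_bc))
  structure(list(k = k, n_barcodes = length(bcs), barcode_length = L, map = map),
            class = "kmer_index")
}

#' Retrieve candidate barcodes for a read window
#'
#' Union of the index hits of all overlapping k-mers of the window. If the
#' window differs from a barcode by at most `e` substitutions and
#' `k <= floor(L / (e + 1))`, the true barcode is guaranteed to be among the
#' candidates (q-gram lemma).
#'
#' @param window A single sequence (may contain `N`; shorter than `k` yields
#'   no candidates).
#' @param index A `kmer_index`.
#' @return Sorted integer vector of 1-based barcode identifiers.
#' @export
query_candidates <- function(window, index) {
  stopifnot(inherits(index, "kmer_index"), length(window) == 1L)
  kms <- unique(.kmers_of(window, index$k))
  if (length(kms) == 0L) return(integer(0))
  sort(unique(unlist(index$map[kms], use.names = FALSE)))
}

#' Largest k-mer length with guaranteed error-free window
#'
#' With `e` erroneous bases in a length-`L` barcode, at least one window of
#' size `floor(L / (e + 1))` must be error-free (pigeonhole), so this k still
#' guarantees index recall; any larger k can be fully covered by the errors.
#'
#' @param L Barcode length.
#' @param e Number of errors to tolerate.
#' @return Integer k; errors if the result would be below 1.
#' @examples
#' recommended_k(18, 2)  # 6
#' @export
recommended_k <- function(L, e) {
  L <- as.integer(L); e <- as.integer(e)
  if (any(e < 0L) || any(L < 1L)) .stopf("need e >= 0 and L >= 1")
  k <- L %/% (e + 1L)
  if (any(k < 1L)) {
    .stopf("no k-mer length can guarantee recall for L = %d with e = %d errors",
           L[which(k < 1L)[1]], e[which(k < 1L)[1]])
  }
  k
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d barcode(s), %d distinct k-mer(s)\n",
              x$k, x$n_barcodes, length(x$map)))
  invisible(x)
}
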