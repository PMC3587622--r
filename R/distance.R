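#' Levenshtein edit distance
#'
#' Minimum number of substitutions, insertions and deletions transforming one
#' string into the other (all operations cost 1). `N` in a read matches
#' nothing: it costs 1 against every base, including another `N`.
#'
#' @param a,b Character vectors of sequences; the shorter one is recycled.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("ACGT", "ACGA")  # 1
#' levenshtein("ACGT", "AGT")   # 1
#' @export
levenshtein <- function(a, b) {
  lev_dist_cpp(as.character(a), as.character(b))
}

#' Padded (wildcard-flanked) edit distance
#'
#' Levenshtein distance computed after flanking both strings with `padding`
#' wildcard positions on each end. A column containing a wildcard costs
#' nothing, whether matched to a base or gapped, so the metric forgives edits
#' that merely shift a sequence within its flanks. This is the distance the
#' design stage screens with: padded sets remain discriminable under
#' insertions and deletions. With `padding = 0` it is exactly
#' [levenshtein()].
#'
#' @param a,b Character vectors of sequences; the shorter one is recycled.
#' @param padding Number of wildcard positions P per flank (>= 0).
#' @return Integer vector of distances; never larger than `levenshtein(a, b)`.
#' @examples
#' padded_distance("ACGTAC", "CGTACA", 1)  # 0: b is a one-base shift of a
#' @export
padded_distance <- function(a, b, padding) {
  padding <- as.integer(padding)
  if (padding < 0L) .stopf("padding must be >= 0")
  padded_dist_cpp(as.character(a), as.character(b), padding)
}

#' Semi-global alignment of a barcode inside a read window
#'
#' Minimum edit distance over all alignments in which every base of the
#' barcode is aligned while the window's flanks are free (cost-free
#' overhangs). Ties on distance are broken deterministically: smallest
#' offset, then fewest indels.
#'
#' @param barcode The pattern sequence, aligned in full.
#' @param window The read window (non-empty); may contain `N`.
#' @param padding Optional wildcard padding applied to the barcode's flanks
#'   before alignment, mirroring the design-stage metric.
#' @return A list with `distance`, `offset` (0-based start of the barcode's
#'   alignment within the window) and `mismatch_positions` (0-based window
#'   positions of the edit columns; exactly `distance` entries).
#' @examples
#' semi_global_align("ACGT", "TTACGTTT")  # distance 0, offset 2
#' @export
semi_global_align <- function(barcode, window, padding = 0L) {
  stopifnot(length(barcode) == 1L, length(window) == 1L)
  if (!nzchar(window)) .stopf("semi_global_align: window must be non-empty")
  sg_align_cpp(barcode, window, as.integer(padding))
}
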