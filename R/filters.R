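#' GC content of a sequence
#'
#' @param s Character vector of DNA sequences (A/C/G/T).
#' @return Numeric vector: fraction of G + C bases, in `[0, 1]`.
#' @examples
#' gc_content(c("ACGT", "AAAA", "GCGC"))
#' @export
gc_content <- function(s) {
  if (any(!nzchar(s)) || any(is.na(s))) .stopf("gc_content: empty sequence")
  (nchar(s) - nchar(gsub("[GCgc]", "", s))) / nchar(s)
}

#' Longest tandem repeat run
#'
#' Maximum number of consecutive tandem copies of any unit of the given
#' length; `unit_length = 1` gives the homopolymer run length in bases.
#'
#' @param s Character vector of DNA sequences.
#' @param unit_length Repeat unit length: 1, 2 or 3.
#' @return Integer vector of maximal tandem copy counts.
#' @examples
#' max_repeat_run("AAACG", 1)     # 3
#' max_repeat_run("ACACACGT", 2)  # 3
#' @export
max_repeat_run <- function(s, unit_length) {
  if (!unit_length %in% 1:3) .stopf("unit_length must be 1, 2 or 3")
  if (any(!nzchar(s)) || any(is.na(s))) .stopf("max_repeat_run: empty sequence")
  u <- as.integer(unit_length)
  vapply(s, function(x) {
    n <- nchar(x)
    if (n < u) return(0L)
    units <- substring(x, seq_len(n - u + 1L), seq_len(n - u + 1L) + u - 1L)
    cnt <- rep(1L, length(units))
    for (i in rev(seq_len(max(0L, length(units) - u)))) {
      if (units[i] == units[i + u]) cnt[i] <- cnt[i + u] + 1L
    }
    max(cnt)
  }, integer(1), USE.NAMES = FALSE)
}

#' Sequence complexity as distinct 3-mer fraction
#'
#' Number of distinct overlapping 3-mers divided by the number of 3-mer
#' windows (`length - 2`). Low-complexity sequences (homopolymers, short
#' tandem repeats) score near 0; a sequence whose 3-mers are all distinct
#' scores 1.
#'
#' @param s Character vector of DNA sequences of length >= 3.
#' @return Numeric vector in `(0, 1]`.
#' @examples
#' complexity_score("AAAAAA")  # 0.25
#' @export
complexity_score <- function(s) {
  if (any(nchar(s) < 3L)) .stopf("complexity_score: sequences must have length >= 3")
  vapply(s, function(x) {
    n <- nchar(x)
    kms <- substring(x, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    length(unique(kms)) / (n - 2L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Double-stranded motif screen
#'
#' Tests whether any motif occurs as a substring of the sequence or of its
#' reverse complement, so that restriction sites are caught on either strand.
#'
#' @param s Character vector of DNA sequences.
#' @param motifs Character vector of motifs; empty means nothing is forbidden.
#' @return Logical vector.
#' @examples
#' contains_motif("AGAATTCA", "GAATTC")  # EcoRI site
#' @export
contains_motif <- function(s, motifs) {
  if (length(motifs) == 0) return(rep(FALSE, length(s)))
  rc <- reverse_complement(s)
  vapply(seq_along(s), function(i) {
    any(vapply(motifs, function(m) {
      grepl(m, s[i], fixed = TRUE) || grepl(m, rc[i], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
}

#' Reverse complement
#'
#' @param s Character vector over A/C/G/T/N.
#' @return Character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(s) {
  .check_dna(toupper(s), allow_n = TRUE, what = "sequence")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.filter_labels <- c("gc", "homopolymer", "dimer_repeat", "trimer_repeat",
                    "complexity", "motif", "revcomp_distance",
                    "self_hyb", "cross_hyb")

# first failed filter label, or NA if all pass; fixed evaluation order:
# GC, repeats, complexity, motifs, revcomp distance, self-hyb, cross-hyb
.first_failure <- function(s, constraints) {
  c <- constraints
  gc <- gc_content(s)
  if (gc < c$gc_min || gc > c$gc_max) return("gc")
  if (max_repeat_run(s, 1L) > c$max_homopolymer) return("homopolymer")
  if (max_repeat_run(s, 2L) > c$max_dimer_repeat) return("dimer_repeat")
  if (max_repeat_run(s, 3L) > c$max_trimer_repeat) return("trimer_repeat")
  if (complexity_score(s) < c$min_complexity) return("complexity")
  if (contains_motif(s, c$forbidden_motifs)) return("motif")
  if (levenshtein(s, reverse_complement(s)) < c$min_revcomp_distance) {
    return("revcomp_distance")
  }
  if (best_self_structure(s)$tm > c$self_hyb_tm_max) return("self_hyb")
  for (p in c$primer_sequences) {
    if (cross_hyb_tm(s, p)$tm > c$cross_hyb_tm_max) return("cross_hyb")
  }
  NA_character_
}

#' Apply the full composition/thermodynamic filter chain
#'
#' Evaluates the sub-filters in a fixed order (GC, homopolymer, dimer repeat,
#' trimer repeat, complexity, forbidden motifs, reverse-complement distance,
#' self-hybridisation, cross-hybridisation) so that the reported first failure
#' is deterministic.
#'
#' @param s A single DNA sequence of the configured barcode length.
#' @param constraints A [design_constraints()] object.
#' @return `TRUE` if all filters pass, otherwise `FALSE` with attribute
#'   `failed_filter` naming the first filter that failed.
#' @examples
#' passes_composition_filters(strrep("A", 18), design_constraints())
#' @export
passes_composition_filters <- function(s, constraints) {
  stopifnot(inherits(constraints, "design_constraints"), length(s) == 1L)
  .check_dna(s, what = "barcode candidate")
  if (nchar(s) != constraints$length) {
    .stopf("candidate length %d does not match configured length %d",
           nchar(s), constraints$length)
  }
  fail <- .first_failure(s, constraints)
  if (is.na(fail)) TRUE else structure(FALSE, failed_filter = fail)
}

#' Tabulate filter outcomes for a set of candidates
#'
#' Tidy wrapper around [passes_composition_filters()].
#'
#' @param s Character vector of candidate sequences.
#' @param constraints A [design_constraints()] object.
#' @return A tibble with columns `sequence`, `passes`, `first_failure`.
#' @export
check_composition <- function(s, constraints) {
  fails <- vapply(s, .first_failure, character(1),
                  constraints = constraints, USE.NAMES = FALSE)
  tibble(sequence = s, passes = is.na(fails), first_failure = fails)
}
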