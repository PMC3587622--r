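#' Strongest predicted self-structure of an oligonucleotide
#'
#' Scans every hairpin decomposition (stem of at least 3 bp closed by a loop
#' of at least 3 nt) and every ungapped self-dimer register, scores each
#' perfectly complementary stem with nearest-neighbor enthalpy/entropy sums
#' (unified parameter set, 50 mM monovalent salt, 0.25 uM strand
#' concentration for bimolecular species), and returns the structure with the
#' highest two-state melting temperature. This is a reject/accept screen
#' against a temperature threshold, not a minimum-free-energy folder: bulges,
#' internal loops and non-canonical pairs are not modelled.
#'
#' @param s A single DNA sequence. Sequences shorter than 8 bases are not
#'   scored and return the no-structure sentinel.
#' @return A list with elements `delta_g` (kcal/mol at 37 C), `tm` (degrees C;
#'   `-Inf` when no stem of at least 3 bp exists), `stem_length` (bp) and
#'   `structure_kind` (`"hairpin"`, `"self-dimer"` or `"none"`).
#' @examples
#' best_self_structure(strrep("A", 18))$tm        # -Inf, no structure
#' best_self_structure("GGGGGCAAAGCCCCC")$structure_kind
#' @export
best_self_structure <- function(s) {
  stopifnot(length(s) == 1L)
  .check_dna(s, what = "sequence")
  thermo_self_cpp(s)
}

#' Strongest cross-hybridisation duplex between a barcode and a primer
#'
#' Maximal-melting-temperature duplex over all ungapped alignment registers
#' of `s` against the reverse complement of `primer`, using the same
#' nearest-neighbor scoring as [best_self_structure()]. Symmetric in its two
#' arguments.
#'
#' @param s,primer DNA sequences (single strings).
#' @return A list as in [best_self_structure()], with
#'   `structure_kind = "cross-dimer"` (or `"none"`).
#' @examples
#' cross_hyb_tm("ACGTACGTACGTACGTAC",
#'              reverse_complement("ACGTACGTACGTACGTAC"))$stem_length
#' @export
cross_hyb_tm <- function(s, primer) {
  stopifnot(length(s) == 1L, length(primer) == 1L)
  if (!nzchar(s) || !nzchar(primer)) .stopf("cross_hyb_tm: empty sequence")
  .check_dna(s, what = "sequence")
  .check_dna(primer, what = "primer")
  thermo_cross_cpp(s, primer)
}
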