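#' Barcode design constraints
#'
#' Bundles every threshold used during barcode design: sequence composition
#' limits, thermodynamic screens, and the distance/padding parameters that
#' define set-level uniqueness. The defaults mirror the tool's standard
#' operating point: GC content between 45% and 65%, homopolymers of at most 4
#' bases, and a self-hybridisation melting-temperature ceiling of 50 degrees C.
#'
#' @param length Barcode length L in bases.
#' @param count Target number of barcodes N.
#' @param gc_min,gc_max Allowed GC-content range, as fractions in `[0, 1]`.
#' @param max_homopolymer Longest allowed single-base run, in bases.
#' @param max_dimer_repeat,max_trimer_repeat Maximum number of consecutive
#'   tandem copies of any 2-mer / 3-mer unit.
#' @param min_complexity Minimum sequence complexity, measured as the fraction
#'   of distinct overlapping 3-mers (see [complexity_score()]).
#' @param self_hyb_tm_max Reject candidates whose strongest hairpin or
#'   self-dimer melts above this temperature (degrees C).
#' @param forbidden_motifs Character vector of motifs (e.g. restriction sites)
#'   that must not occur on either strand.
#' @param primer_sequences Character vector of primer/adapter sequences the
#'   barcodes must not cross-hybridise with.
#' @param cross_hyb_tm_max Reject candidates whose strongest duplex with any
#'   primer melts above this temperature (degrees C).
#' @param min_revcomp_distance Minimum Levenshtein distance between a barcode
#'   and its own reverse complement. Defaults to `min_distance`.
#' @param min_distance Minimum pairwise (padded) edit distance d_min of the
#'   designed set.
#' @param padding Number of wildcard positions P added to each flank when
#'   computing pairwise design distances; padding makes the set tolerant to
#'   insertions/deletions that shift the barcode within the read.
#' @param seed Optional integer seed for reproducible generation.
#'
#' @return An object of class `design_constraints` (a named list).
#' @examples
#' c18 <- design_constraints(length = 18, count = 100, min_distance = 4)
#' c18$gc_min
#' @export
design_constraints <- function(length = 18L, count = 1000L,
                               gc_min = 0.45, gc_max = 0.65,
                               max_homopolymer = 4L,
                               max_dimer_repeat = 3L, max_trimer_repeat = 3L,
                               min_complexity = 0.5,
                               self_hyb_tm_max = 50,
                               forbidden_motifs = character(),
                               primer_sequences = character(),
                               cross_hyb_tm_max = 50,
                               min_revcomp_distance = NULL,
                               min_distance = 4L, padding = 0L,
                               seed = NULL) {
  length <- as.integer(length); count <- as.integer(count)
  min_distance <- as.integer(min_distance); padding <- as.integer(padding)
  if (length < 1L) .stopf("barcode length must be >= 1")
  if (count < 1L) .stopf("barcode count must be >= 1")
  if (min_distance < 1L) .stopf("min_distance must be >= 1")
  if (padding < 0L) .stopf("padding must be >= 0")
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 1)) {
    .stopf("need 0 <= gc_min <= gc_max <= 1 (got %g, %g)", gc_min, gc_max)
  }
  if (min_complexity < 0 || min_complexity > 1) .stopf("min_complexity must be in [0, 1]")
  if (is.null(min_revcomp_distance)) min_revcomp_distance <- min_distance
  forbidden_motifs <- toupper(forbidden_motifs)
  primer_sequences <- toupper(primer_sequences)
  .check_dna(forbidden_motifs, what = "forbidden motif")
  .check_dna(primer_sequences, what = "primer sequence")
  structure(list(
    length = length, count = count,
    gc_min = gc_min, gc_max = gc_max,
    max_homopolymer = as.integer(max_homopolymer),
    max_dimer_repeat = as.integer(max_dimer_repeat),
    max_trimer_repeat = as.integer(max_trimer_repeat),
    min_complexity = min_complexity,
    self_hyb_tm_max = self_hyb_tm_max,
    forbidden_motifs = forbidden_motifs,
    primer_sequences = primer_sequences,
    cross_hyb_tm_max = cross_hyb_tm_max,
    min_revcomp_distance = as.integer(min_revcomp_distance),
    min_distance = min_distance, padding = padding,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "design_constraints")
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("<design_constraints>\n")
  cat(sprintf("  L = %d, N = %d, d_min = %d, padding = %d\n",
              x$length, x$count, x$min_distance, x$padding))
  cat(sprintf("  GC in [%.2f, %.2f], homopolymer <= %d, di/tri repeats <= %d/%d\n",
              x$gc_min, x$gc_max, x$max_homopolymer,
              x$max_dimer_repeat, x$max_trimer_repeat))
  cat(sprintf("  complexity >= %.2f, self-hyb Tm <= %.1f C, cross-hyb Tm <= %.1f C\n",
              x$min_complexity, x$self_hyb_tm_max, x$cross_hyb_tm_max))
  cat(sprintf("  %d forbidden motif(s), %d primer(s)\n",
              length(x$forbidden_motifs), length(x$primer_sequences)))
  invisible(x)
}

#' Read design constraints from a configuration file
#'
#' Parses a plain-text `key=value` configuration (one key per line, `#` starts
#' a comment). Keys match the arguments of [design_constraints()];
#' `forbidden_motifs` takes a comma-separated list, and the additional keys
#' `motifs_fasta` / `primers_fasta` name FASTA files whose sequences are
#' appended to the forbidden motifs / primer list.
#'
#' @param path Path to the configuration file.
#' @return A `design_constraints` object.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) .stopf("cannot parse configuration line: '%s'", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- keys

  args <- list()
  num_keys <- c("length", "count", "gc_min", "gc_max", "max_homopolymer",
                "max_dimer_repeat", "max_trimer_repeat", "min_complexity",
                "self_hyb_tm_max", "cross_hyb_tm_max", "min_revcomp_distance",
                "min_distance", "padding", "seed")
  for (k in intersect(names(vals), num_keys)) args[[k]] <- as.numeric(vals[[k]])
  if ("forbidden_motifs" %in% names(vals)) {
    args$forbidden_motifs <- trimws(strsplit(vals[["forbidden_motifs"]], ",")[[1]])
  }
  if ("primer_sequences" %in% names(vals)) {
    args$primer_sequences <- trimws(strsplit(vals[["primer_sequences"]], ",")[[1]])
  }
  if ("motifs_fasta" %in% names(vals)) {
    args$forbidden_motifs <- c(args$forbidden_motifs, read_fasta_sequences(vals[["motifs_fasta"]]))
  }
  if ("primers_fasta" %in% names(vals)) {
    args$primer_sequences <- c(args$primer_sequences, read_fasta_sequences(vals[["primers_fasta"]]))
  }
  unknown <- setdiff(names(vals), c(num_keys, "forbidden_motifs",
                                    "primer_sequences", "motifs_fasta", "primers_fasta"))
  if (length(unknown)) .stopf("unknown configuration key: '%s'", unknown[1])
  do.call(design_constraints, args)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return An unnamed uppercase character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  toupper(unname(as.character(Biostrings::readDNAStringSet(path))))
}
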