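---
title: "Designing and demultiplexing error-tolerant DNA sample barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and demultiplexing error-tolerant DNA sample barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
library(tibble)
```

## The problem

Pooled sequencing experiments tag each sample's molecules with a short
synthetic DNA sequence (a *barcode* or *index*) so that reads can be assigned
back to their sample after sequencing. Two things can go wrong. First, a
barcode can interfere with the experiment itself — by folding into a hairpin,
hybridising with a primer, or carrying a restriction site. Second, synthesis
and sequencing introduce substitutions, insertions and deletions, so two
barcodes that are too similar can become indistinguishable, or worse, a
corrupted copy of one barcode can look like another.

`barcodekit` addresses both: it designs large sets of barcodes under
user-defined composition constraints with a guaranteed minimum pairwise
Levenshtein distance, and it demultiplexes FASTQ reads back to those barcodes
with a k-mer-accelerated, quality-aware semi-global aligner.

## The distance model

Sequence uniqueness is measured with the Levenshtein (edit) distance: the
minimum number of substitutions, insertions and deletions transforming one
sequence into the other, all at unit cost. Hamming-style designs ignore
indels, yet indels do occur in both synthesis and sequencing; an indel shifts
every downstream base, so a single event can make a Hamming-safe pair
collide.

The central design rule links the set's minimum pairwise distance
$d_{\min}$ to the number of erroneous bases $e$ a read may carry:

$$ d_{\min} \ge 2e + 1. $$

If every pair of barcodes is at distance at least $2e+1$, then a read within
$e$ edits of its true barcode is, by the triangle inequality, at distance at
least $e+1$ from every other barcode — strictly farther than from its own. A
read can then always be classified uniquely, and `recommended_min_distance(e)`
returns this bound. The guarantee is exercised exhaustively in the test
suite: for 50-barcode sets with $d_{\min} = 3$, every possible single edit of
every barcode is classified back correctly.

### Padding: making the metric shift-tolerant

During design the pairwise distance is computed after flanking both
sequences with `padding` wildcard positions per side
(`padded_distance()`). A column containing a wildcard costs nothing, matched
or gapped. The effect is that an alignment may slide one barcode relative to
the other by up to `padding` positions for free — exactly the situation an
insertion or deletion upstream of the barcode creates in a real read. A set
designed with `padding = 0` is safe against substitutions only; designing
with `padding = P` additionally removes pairs that a shift of up to `P`
bases could confuse. The same padding should be mirrored at demultiplexing
time (`demux_params(padding = )`), where it lets edits at the barcode's
flanks be absorbed by the wildcard positions.

Whether wildcards are added to one or both sequences during design screening
is a genuinely open choice; both-sides padding is used because it keeps the
metric symmetric.

## The design procedure

`generate_barcodes()` is a greedy randomized search:

1. Draw a uniform random length-$L$ candidate whose GC content lands in the
   configured range (rejection sampling, so the draw is uniform over the
   admissible sequences).
2. Run the composition filter chain, in a fixed order so failure labels are
   deterministic: GC content, homopolymer run, dimer repeat, trimer repeat,
   complexity, forbidden motifs (both strands), distance to the candidate's
   own reverse complement, self-hybridisation, cross-hybridisation with
   primers.
3. Accept the candidate iff its padded distance to every previously accepted
   barcode is at least $d_{\min}$; `min` over the accepted set may be
   computed in any partition order without changing the outcome.

Acceptance is first-fit in arrival order, so a fixed seed reproduces the set
bit for bit. When `max_attempts` (default $1000 \times N$) is exhausted the
partial set is returned with a tally of filter failures and distance
rejections — impossible constraint combinations terminate with a report, not
an infinite loop. The acceptance threshold is $\ge d_{\min}$, so
`min_distance` is documented as the minimum *attained* distance of the set.

### Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `gc_min`, `gc_max` | 0.45, 0.65 | fraction | balanced melting behaviour |
| `max_homopolymer` | 4 | bases | homopolymer runs inflate indel rates |
| `max_dimer_repeat`, `max_trimer_repeat` | 3 | tandem copies | repeat degeneracy |
| `min_complexity` | 0.5 | fraction | see below |
| `self_hyb_tm_max` | 50 | degrees C | hairpins/self-dimers interfere with library prep |
| `cross_hyb_tm_max` | 50 | degrees C | primer interference |
| `min_revcomp_distance` | `min_distance` | edits | a barcode colliding with its own reverse complement breaks strand-agnostic use |
| `min_distance` | 4 | edits | tolerates $e = 1$ with margin; see $2e+1$ rule |
| `padding` | 0 | positions | substitution-only designs |

The complexity measure is the fraction of distinct overlapping 3-mers
(`complexity_score()`). There is no single standard definition of
low-complexity for oligos this short; the distinct-3-mer fraction was chosen
because it is cheap, monotone with linguistic complexity, and directly
catches the repeat degeneracies the other filters aim at. The di-/tri-mer
repeat default of 3 tandem copies is likewise this package's own choice.

## The thermodynamic screen

Full minimum-free-energy folding is more machinery than an accept/reject
screen needs. `best_self_structure()` instead enumerates every hairpin
decomposition (stem $\ge$ 3 bp, loop $\ge$ 3 nt — standard hairpin geometry)
and every ungapped self-dimer register, scores each perfectly complementary
stem with unified nearest-neighbor $\Delta H$/$\Delta S$ sums, and converts
to a two-state melting temperature:

* hairpins (unimolecular): $T_m = \Delta H / (\Delta S_{\text{stem}} +
  \Delta S_{\text{loop}})$, with the loop entropy extrapolated
  Jacobson–Stockmayer-style from a 3.5 kcal/mol tri-loop penalty;
* dimers (bimolecular): $T_m = \Delta H / (\Delta S + R \ln(C_T/4))$ at a
  strand concentration of 0.25 µM, with terminal A·T/G·C initiation
  penalties;
* both with an entropic salt correction for 50 mM monovalent cations.

Bulges, internal loops and non-canonical pairs are not modelled, and the
salt/concentration conditions are fixed. Because the value is only compared
against a threshold (default 50 °C), the tests assert threshold behaviour on
extreme constructs — a 10 bp GC stem is always rejected, a sequence with no
complementary stretch of 3 bases is always accepted — rather than absolute
Tm accuracy. One consequence of the two-state model worth knowing: a strong
hairpin can legitimately melt *above* the bimolecular duplex of the same
sequence with its reverse complement, because the unimolecular transition
has no concentration term.

## Demultiplexing

`demultiplex()` assigns each read in four steps:

1. **Window extraction.** The read substring
   $[\max(0, s - p_e),\ \min(\text{len}, s + L + p_e))$ around the declared
   barcode start $s$, where the positional error $p_e$ allows for indels
   upstream of the barcode; $p_e = -1$ scans the whole read (slower and less
   accurate). Coordinates are 0-based, intervals half-open.
2. **Candidate retrieval.** A hash index maps every k-mer of every barcode
   to the barcodes containing it (`build_kmer_index()`); the union of hits
   over the window's k-mers is the candidate set. By the q-gram lemma, a
   window with at most $e$ substitutions still shares an intact k-mer with
   its barcode whenever $k \le \lfloor L/(e+1) \rfloor$
   (`recommended_k()`); for $L = 18$ and $e = 2$ this gives $k = 6$.
   Larger k shrinks candidate lists but loses reads whose errors cover every
   window — the accuracy-versus-speed trade the k flag exposes.
3. **Alignment.** Every candidate is aligned semi-globally: the whole
   barcode must align, the window's flanks are free. Ties on distance break
   deterministically (smallest offset, then fewest indels). `N` in a read
   matches nothing — it costs 1 against every base, which is the
   conservative choice toward ambiguity.
4. **Status.** With $d^\ast$ the best distance: `unmatched` if
   $d^\ast >$ `max_distance` (default $\lfloor d_{\min}/2 \rfloor$, the
   largest cut-off for which the $2e+1$ guarantee applies); `matched` if one
   candidate is strictly best; otherwise the quality tie-break sums the
   Phred scores at each candidate's mismatch positions and the *lowest* sum
   wins — its mismatches sit on the least trustworthy bases, so sequencing
   error is the most plausible explanation. Surviving ties are `ambiguous`;
   a read equidistant from two barcodes under uniform qualities is never
   forced into a match.

Per-read decisions are independent, so any processing order gives identical
results; output is reported in input order. Paired-end input is classified
on read 1 and the mate inherits the assignment. Matched FASTQ records carry
`+BC:<sequence> ID:<id> ED:<distance>` on the separator line (the annotated
separator layout is this package's own definition).

## The read simulator

`simulate_reads()` generates the inputs for accuracy evaluation: each read
picks a barcode uniformly, places it at the configured start, fills flanks
with uniform random bases, then walks the template base by base — delete
with probability `deletion`, otherwise substitute (to a uniformly different
base) with probability `substitution`, and insert a uniform base after the
position with probability `insertion`. Qualities are constant Q30 so that
quality tie-breaking is exercised separately with hand-built fixtures, not
confounded into the accuracy figures. `split_error_model(total)` divides a
total per-base error rate 80/10/10 among substitution/insertion/deletion;
the split is a package choice, with each rate independently configurable.

What the simulator does *not* emulate: platform-specific quality profiles,
GC bias, PCR duplicates, or error clustering. Passing accuracy tests on
simulated reads therefore demonstrates the geometry of the method — distance
guarantees, index recall, tie handling — not robustness to every real-world
artefact.

## Study conditions used in the checks

The accuracy checks in `scripts/acceptance.R` and the test suite run at desk
scale, chosen as this package's standard evaluation sizes:

* substitution-only: 2,000 barcodes ($L = 18$, $d_{\min} = 4$, no padding),
  50,000 length-18 reads at 2% per-base substitution errors, demultiplexed
  at $k = 6$, positional error 0;
* indel-inclusive: 1,000 barcodes designed with padding 1, 50,000 reads at
  2% total error including indels, demultiplexed at $k = 6$, positional
  error 1.

Under these conditions essentially every read is either correctly matched or
(for the ~0.5% of reads carrying three or more errors, beyond the
`max_distance = 2` cut-off) reported unmatched; wrong and ambiguous calls
are zero or within a read or two of zero. Raising k to 9 on the same reads
demonstrably loses reads: two errors can then cover every length-9 window,
so the true barcode drops out of the candidate list.

## Numerical and degenerate-input choices

* All edit costs are unit; no affine gap model.
* The distance screen uses an early-exit (row-minimum cut-off) dynamic
  program, so design-time screening and demultiplexing never pay for
  distances beyond the decision threshold; correctness is oracle-tested
  against plain DP.
* Empty windows (barcode start beyond the read end) classify as
  `unmatched`, never an error; reads shorter than the barcode are allowed
  and simply pay the alignment cost of the missing bases.
* Barcode identifiers are 1-based row numbers of the barcode list.
* The distance histogram uses the padded design metric, since that is the
  screening distance the set guarantees.

## Limitations

* The greedy search makes no optimality claim about set size; it reproduces
  the randomized first-fit procedure, not a maximal code construction.
* The thermodynamic screen is a stem-enumeration approximation, suitable
  only as a threshold filter.
* Qualities are assumed Sanger Phred+33; other encodings are out of scope,
  as are barcode trimming, sample sheets and BAM/SAM output.
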