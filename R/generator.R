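new_barcode_set <- function(barcodes, constraints, report) {
  structure(list(
    barcodes = barcodes,
    length = constraints$length,
    min_distance = constraints$min_distance,
    padding = constraints$padding,
    constraints = constraints,
    report = report
  ), class = "barcode_set")
}

# accept a barcode_set or a bare character vector wherever barcodes are needed
.bc_chr <- function(set) {
  if (inherits(set, "barcode_set")) set$barcodes else as.character(set)
}

#' Draw one random candidate barcode
#'
#' Uniform random length-L sequence, rejection-sampled until its GC content
#' falls inside the configured range (so the draw is uniform over all
#' sequences satisfying the GC bounds). Uses the current R random number
#' generator state, so results are reproducible under [set.seed()].
#'
#' @param constraints A [design_constraints()] object.
#' @return A single sequence of length `constraints$length`.
#' @export
random_candidate <- function(constraints) {
  L <- constraints$length
  repeat {
    s <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    gc <- gc_content(s)
    if (gc >= constraints$gc_min && gc <= constraints$gc_max) return(s)
  }
}

#' Attempt to add a candidate to a barcode set
#'
#' The candidate is accepted iff its padded distance to every already
#' accepted barcode is at least the set's minimum distance. The scan over
#' the accepted set is order-independent: the outcome equals a sequential
#' scan regardless of how the comparisons are partitioned.
#'
#' @param set A `barcode_set` (possibly empty).
#' @param candidate A candidate sequence that already passed the
#'   composition/thermo filters.
#' @return A list with `accepted` (logical) and `set` (the possibly grown
#'   `barcode_set`).
#' @export
try_insert <- function(set, candidate) {
  stopifnot(inherits(set, "barcode_set"))
  ok <- length(set$barcodes) == 0L ||
    min_dist_to_set_cpp(candidate, set$barcodes, set$padding,
                        set$min_distance - 1L) >= set$min_distance
  if (ok) set$barcodes <- c(set$barcodes, candidate)
  list(accepted = ok, set = set)
}

#' Generate a barcode set by greedy randomized search
#'
#' Repeatedly draws random candidates, applies the composition and
#' thermodynamic filter chain, and accepts a candidate into the growing set
#' only if its padded edit distance to every accepted barcode is at least
#' `min_distance`. Acceptance is greedy first-fit in candidate arrival
#' order, which makes a run bit-reproducible from its seed. If
#' `max_attempts` candidates are exhausted before the target count is
#' reached, the partial set is returned together with a report; impossible
#' constraint combinations therefore terminate with a report rather than
#' looping forever.
#'
#' @param constraints A [design_constraints()] object.
#' @param max_attempts Maximum number of candidate draws (default
#'   `1000 * count`).
#' @param seed Integer seed; defaults to `constraints$seed`. `NULL` leaves
#'   the RNG state untouched.
#' @return A `barcode_set`: barcodes plus a generation report
#'   (`attempts`, `filter_failures`, `distance_rejections`, `completed`).
#' @examples
#' set <- generate_barcodes(design_constraints(length = 12, count = 10,
#'                                             min_distance = 3, seed = 1))
#' length(set$barcodes)
#' @export
generate_barcodes <- function(constraints,
                              max_attempts = 1000L * constraints$count,
                              seed = constraints$seed) {
  stopifnot(inherits(constraints, "design_constraints"))
  if (max_attempts < constraints$count) {
    .stopf("max_attempts (%d) must be at least the target count (%d)",
           max_attempts, constraints$count)
  }
  run <- function() {
    accepted <- character(0)
    failures <- integer(length(.filter_labels))
    names(failures) <- .filter_labels
    dist_rej <- 0L
    attempts <- 0L
    P <- constraints$padding
    d_min <- constraints$min_distance
    while (length(accepted) < constraints$count && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- random_candidate(constraints)
      fail <- .first_failure(cand, constraints)
      if (!is.na(fail)) {
        failures[fail] <- failures[fail] + 1L
        next
      }
      if (length(accepted) == 0L ||
          min_dist_to_set_cpp(cand, accepted, P, d_min - 1L) >= d_min) {
        accepted <- c(accepted, cand)
      } else {
        dist_rej <- dist_rej + 1L
      }
    }
    report <- list(attempts = attempts,
                   filter_failures = failures,
                   distance_rejections = dist_rej,
                   completed = length(accepted) == constraints$count)
    new_barcode_set(accepted, constraints, report)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Minimum design distance needed to tolerate a given error load
#'
#' For reads expected to carry at most `expected_errors` erroneous bases, a
#' set whose pairwise distance is more than twice that number (`2e + 1`)
#' guarantees that an errored barcode stays strictly closer to its original
#' than to any other set member, so it can always be classified uniquely.
#'
#' @param expected_errors Expected number of erroneous bases per barcode.
#' @return Integer: `2 * expected_errors + 1`.
#' @examples
#' recommended_min_distance(1)  # 3
#' @export
recommended_min_distance <- function(expected_errors) {
  expected_errors <- as.integer(expected_errors)
  if (any(expected_errors < 0L)) .stopf("expected_errors must be >= 0")
  2L * expected_errors + 1L
}

#' Pairwise distance histogram of a barcode set
#'
#' Padded distances (the design screening metric, using the set's own
#' padding) over all unordered pairs.
#'
#' @param set A `barcode_set` or character vector of barcodes.
#' @param padding Padding to use when `set` is a bare character vector.
#' @return A tibble with columns `distance` and `pair_count`, ascending in
#'   distance, containing only distances with at least one pair. Counts sum
#'   to `n * (n - 1) / 2`.
#' @export
distance_histogram <- function(set, padding = NULL) {
  bcs <- .bc_chr(set)
  if (is.null(padding)) {
    padding <- if (inherits(set, "barcode_set")) set$padding else 0L
  }
  if (length(bcs) < 2L) {
    return(tibble(distance = integer(), pair_count = integer()))
  }
  counts <- pair_dist_counts_cpp(bcs, as.integer(padding))
  d <- seq_along(counts) - 1L
  keep <- counts > 0L
  tibble(distance = d[keep], pair_count = counts[keep])
}

#' Write a barcode list
#'
#' One sequence per line, no header; round-trips through [read_barcodes()].
#'
#' @param set A `barcode_set` or character vector.
#' @param path Output path.
#' @export
write_barcodes <- function(set, path) {
  writeLines(.bc_chr(set), path)
  invisible(path)
}

#' Read a barcode list
#'
#' @param path Path to a plain-text file, one barcode per line.
#' @return Character vector of uppercase barcodes (all the same length).
#' @export
read_barcodes <- function(path) {
  bcs <- toupper(trimws(readLines(path, warn = FALSE)))
  bcs <- bcs[nzchar(bcs)]
  .check_dna(bcs, what = "barcode")
  if (length(bcs) && length(unique(nchar(bcs))) != 1L) {
    .stopf("barcodes in '%s' have unequal lengths", path)
  }
  bcs
}

#' Write a pairwise-distance histogram
#'
#' Tab-separated `distance<TAB>pair_count` rows in ascending distance order,
#' no header.
#'
#' @param hist A tibble as returned by [distance_histogram()].
#' @param path Output path.
#' @export
write_histogram <- function(hist, path) {
  hist <- hist[order(hist$distance), ]
  writeLines(sprintf("%d\t%d", hist$distance, hist$pair_count), path)
  invisible(path)
}

#' Audit a barcode set against its own guarantees
#'
#' Recomputes, independently of the generation bookkeeping, the all-pairs
#' padded-distance minimum and re-applies the composition filter chain to
#' every member.
#'
#' @param set A `barcode_set`.
#' @return A list with `min_pairwise_distance`, `all_pass_filters` and the
#'   full `histogram` tibble.
#' @export
audit_barcode_set <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  hist <- distance_histogram(set)
  comp <- check_composition(set$barcodes, set$constraints)
  list(
    min_pairwise_distance = if (nrow(hist)) min(hist$distance) else NA_integer_,
    all_pass_filters = all(comp$passes),
    histogram = hist
  )
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("<barcode_set> %d barcode(s), L = %d, d_min = %d, padding = %d\n",
              length(x$barcodes), x$length, x$min_distance, x$padding))
  cat(sprintf("  generation: %d attempt(s), %d distance rejection(s), %s\n",
              x$report$attempts, x$report$distance_rejections,
              if (x$report$completed) "completed" else "EXHAUSTED (partial set)"))
  if (length(x$barcodes)) {
    cat("  first barcodes:", paste(head(x$barcodes, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' @describeIn generate_barcodes Per-barcode composition summary as a tibble.
#' @param x A `barcode_set`.
#' @param ... Unused.
#' @method tidy barcode_set
#' @export
tidy.barcode_set <- function(x, ...) {
  bcs <- x$barcodes
  tibble(
    barcode_id = seq_along(bcs),
    sequence = bcs,
    gc = gc_content(bcs),
    max_homopolymer = max_repeat_run(bcs, 1L),
    complexity = complexity_score(bcs)
  )
}

#' @describeIn generate_barcodes One-row generation summary.
#' @method glance barcode_set
#' @export
glance.barcode_set <- function(x, ...) {
  tibble(
    n_barcodes = length(x$barcodes),
    length = x$length,
    min_distance = x$min_distance,
    padding = x$padding,
    attempts = x$report$attempts,
    filter_rejections = sum(x$report$filter_failures),
    distance_rejections = x$report$distance_rejections,
    completed = x$report$completed
  )
}

#' @describeIn generate_barcodes Pairwise-distance histogram plot.
#' @param object A `barcode_set`.
#' @method autoplot barcode_set
#' @export
autoplot.barcode_set <- function(object, ...) {
  hist <- distance_histogram(object)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$distance, y = .data$pair_count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$min_distance - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "pairwise padded edit distance", y = "barcode pairs",
                  title = sprintf("%d barcodes, d_min = %d, padding = %d",
                                  length(object$barcodes), object$min_distance,
                                  object$padding)) +
    ggplot2::theme_minimal()
}
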