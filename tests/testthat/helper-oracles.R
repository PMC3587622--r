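# Independent oracles used across the suite. These deliberately re-derive the
# quantities with different machinery than the package kernels.

rand_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# plain Levenshtein oracle (base R)
lev_oracle <- function(a, b) as.integer(utils::adist(a, b))

# padded-distance oracle: explicit DP over wildcard-padded strings
padded_oracle <- function(a, b, P) {
  pad <- function(s) paste0(strrep("*", P), s, strrep("*", P))
  x <- strsplit(pad(a), "")[[1]]
  y <- strsplit(pad(b), "")[[1]]
  sub <- function(p, q) if (p == "*" || q == "*") 0L else if (p == q) 0L else 1L
  gap <- function(p) if (p == "*") 0L else 1L
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) D[i + 1, 1] <- D[i, 1] + gap(x[i])
  for (j in seq_len(m)) D[1, j + 1] <- D[1, j] + gap(y[j])
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + sub(x[i], y[j]),
                             D[i, j + 1] + gap(x[i]),
                             D[i + 1, j] + gap(y[j]))
    }
  }
  D[n + 1, m + 1]
}

# semi-global oracle: minimum Levenshtein distance of the barcode to any
# substring of the window (including the empty substring)
sg_oracle <- function(bc, win) {
  n <- nchar(win)
  best <- nchar(bc)  # empty substring
  for (i in seq_len(n)) {
    for (j in i:n) {
      best <- min(best, lev_oracle(bc, substr(win, i, j)))
    }
  }
  best
}

# brute-force repeat-run oracle: direct forward comparison of unit copies
repeat_run_oracle <- function(s, u) {
  n <- nchar(s)
  if (n < u) return(0L)
  best <- 1L
  for (start in seq_len(n - u + 1L)) {
    unit <- substr(s, start, start + u - 1L)
    copies <- 1L
    pos <- start + u
    while (pos + u - 1L <= n && substr(s, pos, pos + u - 1L) == unit) {
      copies <- copies + 1L
      pos <- pos + u
    }
    best <- max(best, copies)
  }
  best
}

gc_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("G", "C"))
}

complexity_oracle <- function(s) {
  n <- nchar(s)
  kms <- character(n - 2L)
  for (i in seq_len(n - 2L)) kms[i] <- substr(s, i, i + 2L)
  length(unique(kms)) / (n - 2L)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# longest perfectly complementary antiparallel run between a and b, by
# exhaustive position pairs
longest_complementary_run <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- 0L
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      r <- 0L
      while (i + r <= length(x) && j - r >= 1L &&
             comp_base[[x[i + r]]] == y[j - r]) {
        r <- r + 1L
      }
      best <- max(best, r)
    }
  }
  best
}

# all strings over ACGT up to a given length
all_dna_upto <- function(max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), len))
    out <- c(out, apply(as.matrix(grid), 1L, paste, collapse = ""))
  }
  out
}

# apply a single named edit to a sequence (1-based position)
apply_edit <- function(s, type, pos, base = "A") {
  n <- nchar(s)
  switch(type,
    sub = paste0(substr(s, 1, pos - 1), base, substr(s, pos + 1, n)),
    del = paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n)),
    ins = paste0(substr(s, 1, pos), base, substr(s, pos + 1, n))
  )
}
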