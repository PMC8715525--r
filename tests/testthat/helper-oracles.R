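# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: coverage by naive per-position extension, local
# alignment by explicit path enumeration or plain memoised recursion.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Union coverage of every perfect tandem repeat (start, period, copies >=
# min_copies): for each start and period, walk right residue by residue
# while the sequence keeps repeating perfectly.
oracle_perfect_coverage <- function(s, min_copies = 2, max_period = 60) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  cov <- logical(L)
  if (L < 2) return(0L)
  for (p in seq_len(min(max_period, L %/% 2))) {
    for (st in seq_len(L - 2 * p + 1)) {
      len <- p
      while (st + len <= L && ch[st + len] == ch[st + len - p]) len <- len + 1
      if (len / p >= min_copies) cov[st:(st + len - 1)] <- TRUE
    }
  }
  sum(cov)
}

# Optimal local alignment score by enumerating every alignment path
# (exponential; only for very short sequences). Gap of length k costs
# go + k * ge, matching the package convention.
oracle_enum_local <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  if (m == 0 || n == 0) return(0)
  best <- 0
  rec <- function(i, j, sc, lastgap) {
    best <<- max(best, sc)
    if (i < m && j < n) rec(i + 1, j + 1, sc + mat[A[i + 1], B[j + 1]], 0L)
    if (j < n) rec(i, j + 1, sc - (if (lastgap == 1L) ge else go + ge), 1L)
    if (i < m) rec(i + 1, j, sc - (if (lastgap == 2L) ge else go + ge), 2L)
  }
  for (i in 0:(m - 1)) for (j in 0:(n - 1))
    rec(i + 1, j + 1, mat[A[i + 1], B[j + 1]], 0L)
  best
}

# Independent memoised three-state recursion for affine local alignment
# (top-down, written separately from the package's iterative C++ kernel).
oracle_rec_local <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  if (m == 0 || n == 0) return(0)
  memo <- array(NA_real_, dim = c(m + 1, n + 1, 3))
  # state 1: alignment ends in a substitution at (i, j)
  # state 2: ends in a gap consuming B[j]; state 3: gap consuming A[i]
  sc <- function(i, j, st) {
    if (i == 0 || j == 0) return(-Inf)
    v <- memo[i + 1, j + 1, st]
    if (!is.na(v)) return(v)
    v <- if (st == 1) {
      mat[A[i], B[j]] +
        max(0, sc(i - 1, j - 1, 1), sc(i - 1, j - 1, 2), sc(i - 1, j - 1, 3))
    } else if (st == 2) {
      max(max(sc(i, j - 1, 1), sc(i, j - 1, 3)) - go - ge,
          sc(i, j - 1, 2) - ge)
    } else {
      max(max(sc(i - 1, j, 1), sc(i - 1, j, 2)) - go - ge,
          sc(i - 1, j, 3) - ge)
    }
    memo[i + 1, j + 1, st] <<- v
    v
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) best <- max(best, sc(i, j, 1))
  best
}

# Small deterministic study for screen-level tests.
tiny_config <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_decoys = 40L, contaminant_count = 3L,
               n_species = 4L, n_decoy_transcripts = 10L, ...)
}
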