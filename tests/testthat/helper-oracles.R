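# Independent oracles used across the suite.

# Exhaustive depth-first search for the longest front-to-back (x
# non-increasing) path of pairwise-sequential agents. Completely independent
# of the package's DP-based chain detector.
oracle_chain_length <- function(x, y) {
  n <- length(x)
  seq_mat <- outer(x, x, function(a, b) abs(a - b) <= 4) &
    outer(y, y, function(a, b) abs(a - b) <= 1)
  best <- 1L
  rec <- function(last, used, len) {
    if (len > best) best <<- len
    if (best == n) return()
    for (j in seq_len(n)) {
      if (!used[j] && seq_mat[last, j] && x[j] <= x[last]) {
        used[j] <- TRUE
        rec(j, used, len + 1L)
        used[j] <- FALSE
      }
    }
  }
  for (i in seq_len(n)) {
    used <- rep(FALSE, n)
    used[i] <- TRUE
    rec(i, used, 1L)
  }
  best
}

# random agent placement on a small box, mixing sparse and dense cases
random_placement <- function(n = 8, xmax = 14, ymax = 6) {
  repeat {
    pos <- cbind(sample.int(xmax + 1, n, replace = TRUE) - 1L,
                 sample.int(ymax + 1, n, replace = TRUE) - 1L)
    if (!anyDuplicated(pos)) return(pos)
  }
}

expect_rel_close <- function(value, target, tol) {
  expect_true(
    abs(value - target) <= tol * abs(target),
    label = sprintf("%.4g within %.0f%% of %.4g", value, 100 * tol, target)
  )
}
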