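# Independent brute-force oracles used by module and acceptance tests.
# These deliberately re-derive results by exhaustive scanning, not by calling
# the implementation under test.

# All maximal runs of scores > threshold with length >= min_len, by linear scan.
brute_segments <- function(scores, threshold = 0.5, min_len = 31L) {
  above <- scores > threshold
  n <- length(scores)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Exhaustive FDR threshold search: most permissive observed score whose
# decoy/target ratio among entities scoring >= it is <= target.
brute_fdr_threshold <- function(scores, is_decoy, target) {
  best <- NULL
  for (s in sort(unique(scores))) {
    keep <- scores >= s
    d <- sum(is_decoy[keep]); t <- sum(!is_decoy[keep])
    fdr <- if (t == 0) ifelse(d == 0, 0, Inf) else d / t
    if (fdr <= target) { best <- s; break }  # ascending scan: first valid is most permissive
  }
  best
}

# Exhaustive pairwise strict-subset analysis on peptide sets.
brute_parsimony_survivors <- function(sets) {
  ids <- names(sets)
  keep <- vapply(seq_along(sets), function(i) {
    if (length(sets[[i]]) == 0L) return(FALSE)
    !any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  # among keepers, identical sets collapse to the lexicographically smallest id
  kept <- ids[keep]
  keys <- vapply(sets[kept], paste, character(1), collapse = "\r")
  vapply(split(kept, keys), min, character(1), USE.NAMES = FALSE)
}

# Closed-form FRAP models, written out independently of the package.
single_exp_curve <- function(t, plateau, f0, tau) {
  plateau - (plateau - f0) * exp(-t / tau)
}
double_exp_curve <- function(t, plateau, af, tf, as_, ts) {
  plateau - af * exp(-t / tf) - as_ * exp(-t / ts)
}

# Quick random profile generator for segmentation tests.
random_profile <- function(n, id = "rp") {
  disorder_profile(id, runif(n))
}
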