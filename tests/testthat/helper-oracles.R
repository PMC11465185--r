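# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by direct enumeration or a reference library and
# share no code with the implementations they check.

# N50 by scanning every candidate length
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
  min(lengths)
}

# longest qualifying run by scanning every start/end pair
oracle_persistence <- function(values, threshold = 0.20) {
  n <- length(values)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    if (all(values[i:j] > threshold)) best <- max(best, j - i + 1L)
  }
  best
}

# TIR by explicit prefix/suffix comparison at every length
oracle_tir <- function(seq, min_len = 20, window = 5000, max_mismatch_frac = 0.05) {
  n <- nchar(seq)
  w <- min(window, floor(n / 2))
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- function(v) rev(chartr("ACGT", "TGCA", v))
  best <- NULL
  if (w >= min_len) for (L in min_len:w) {
    pref <- x[1:L]
    suf <- x[(n - L + 1):n]
    mm <- sum(pref != rc(suf))
    if (mm / L <= max_mismatch_frac)
      best <- list(repeat_length = L, start_offset = 0L, mismatches = mm)
  }
  best
}

# all multisets of size <= max_k drawn from a universe of lengths
all_multisets <- function(universe, max_k) {
  out <- list()
  for (k in seq_len(max_k)) {
    idx <- utils::combn(length(universe) + k - 1, k)
    for (j in seq_len(ncol(idx))) {
      pick <- idx[, j] - seq(0, k - 1)
      out[[length(out) + 1]] <- universe[pick]
    }
  }
  out
}

# deterministic random DNA for fixtures
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
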