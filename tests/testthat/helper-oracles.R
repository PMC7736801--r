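# Independent oracles used to cross-check the package implementations.

# Plain-R local affine-gap alignment score: the exact collapse of the
# enumeration over all local alignments, written as an explicit
# three-state recurrence independent of the package's C++ code.
sw_score_oracle <- function(query, reference, match, mismatch,
                            gap_open, gap_extend) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (q[i] == r[j] && q[i] != "N") match else mismatch
    E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Brute-force discrete Gaussian convolution with whole-sample reflection,
# computed position by position.
gc_conv_oracle <- function(sequence, sigma) {
  chars <- strsplit(sequence, "")[[1]]
  ind <- as.numeric(chars %in% c("G", "C"))
  n <- length(ind)
  h <- ceiling(4 * sigma)
  k <- dnorm(-h:h, 0, sigma); k <- k / sum(k)
  reflect <- function(p) { # 0-based triangle wave over 0..n-1
    per <- 2 * n - 2
    if (per <= 0) return(0L)
    p <- p %% per
    if (p >= n) per - p else p
  }
  vapply(seq_len(n) - 1L, function(p) {
    sum(vapply(-h:h, function(o) k[o + h + 1] * ind[reflect(p + o) + 1],
               numeric(1)))
  }, numeric(1))
}

# Build a calls data frame straight from the simulator's reported truth
# flags (perfect detection), bypassing intensities.
truth_to_calls <- function(truths) {
  chans <- setdiff(names(truths), c("index", "captured", "contaminants"))
  do.call(rbind, lapply(chans, function(ch)
    data.frame(index = truths$index, channel = ch,
               occupied = truths[[ch]],
               posterior = as.numeric(truths[[ch]]))))
}

# Enumerate every joint linearization of a set-read (test-side
# implementation, independent of best_order_search's recursion).
all_linearizations <- function(read) {
  perms <- lapply(read$droplets, dropseqr:::distinct_perms)
  grid <- do.call(expand.grid, c(perms, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

# Well-separated intensity model for tests that need near-perfect calls.
separated_model <- function() {
  intensity_model(c(2, 0.05), c(4, 0.05), occupied_weight = 0.3)
}
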