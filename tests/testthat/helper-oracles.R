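# Independent brute-force oracles: literal formula transcriptions with
# explicit loops, kept free of the package's vectorized implementations.

oracle_rmssd <- function(iv) {
  s <- 0
  n <- 0
  for (i in seq_len(length(iv) - 1)) {
    s <- s + (iv[i + 1] - iv[i])^2
    n <- n + 1
  }
  sqrt(s / n)
}

oracle_cv <- function(iv) {
  m <- sum(iv) / length(iv)
  ss <- 0
  for (v in iv) ss <- ss + (v - m)^2
  sqrt(ss / (length(iv) - 1)) / m
}

oracle_shannon_entropy <- function(iv, n_bins = 16) {
  lo <- min(iv)
  hi <- max(iv)
  if (hi == lo) {
    return(0)
  }
  counts <- rep(0, n_bins)
  width <- (hi - lo) / n_bins
  for (v in iv) {
    b <- floor((v - lo) / width) + 1
    if (b > n_bins) b <- n_bins
    if (b < 1) b <- 1
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / length(iv)
      h <- h - p * log(p)
    }
  }
  h / log(n_bins)
}

# AUC by exhaustive pair counting, ties worth one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "AF"]
  neg <- scores[labels == "SR"]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# Admissible window starts by direct enumeration under the strict-end rule.
oracle_n_windows <- function(duration, window, stride, fs = 50) {
  if (abs(duration - window) < 0.5 / fs) {
    return(1L)
  }
  n <- 0L
  start <- 0
  while (TRUE) {
    if (start + window <= duration - 0.5 / fs) {
      n <- n + 1L
    } else {
      break
    }
    start <- start + stride
  }
  n
}
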