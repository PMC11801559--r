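# Independent brute-force oracles; deliberately naive double loops so they
# share no code path with the package implementations they check.

oracle_local_extrema <- function(x, window) {
  half <- (window - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  mx <- mn <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - half):(i + half), 1L), h)  # replicate padding
      rj <- pmin(pmax((j - half):(j + half), 1L), w)
      patch <- x[ri, rj]
      mx[i, j] <- max(patch)
      mn[i, j] <- min(patch)
    }
  }
  list(local_max = mx, local_min = mn)
}

oracle_average_gradient <- function(x255) {
  m <- nrow(x255); n <- ncol(x255)
  acc <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq_len(n - 1L)) {
      dx <- x255[i + 1L, j] - x255[i, j]
      dy <- x255[i, j + 1L] - x255[i, j]
      acc <- acc + sqrt((dx^2 + dy^2) / 2)
    }
  }
  acc / ((m - 1L) * (n - 1L))
}

oracle_entropy <- function(levels0_255) {
  h <- 0
  n <- length(levels0_255)
  for (k in 0:255) {
    p <- sum(levels0_255 == k) / n
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# direct scalar transcription of the Hamacher sum with parameter lambda
oracle_hamacher <- function(a, b, lambda) {
  (a + b - (2 - lambda) * a * b) / (1 - (1 - lambda) * a * b)
}

rand_norm_image <- function(h, w) matrix(stats::runif(h * w), h, w)
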