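# Independent oracles and small utilities shared across tests.

# central finite difference of a scalar function
fd_derivative <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

fd_second_derivative <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# brute-force O(n^2) all-to-first-passage scan over crossing times:
# for every start-crossing, search forward for the next target-crossing
brute_force_passages <- function(time, position, start, target) {
  # same convention as the package, implemented independently: samples
  # sitting exactly on the level carry the preceding sign (explicit loop)
  cross_times <- function(level) {
    d <- position - level
    n <- length(d)
    s <- sign(d)
    last <- 0
    for (i in seq_len(n)) {
      if (s[i] == 0) s[i] <- last else last <- s[i]
    }
    first_nz <- which(s != 0)[1]
    if (is.na(first_nz)) return(numeric(0))
    if (first_nz > 1) s[seq_len(first_nz - 1)] <- s[first_nz]
    idx <- which(s[-n] != s[-1])
    time[idx] + (time[idx + 1] - time[idx]) * (level - position[idx]) /
      (position[idx + 1] - position[idx])
  }
  S <- cross_times(start)
  Tt <- cross_times(target)
  durations <- numeric(0)
  arrivals <- numeric(0)
  for (s in S) {
    later <- Tt[Tt > s]
    if (length(later)) {
      durations <- c(durations, min(later) - s)
      arrivals <- c(arrivals, min(later))
    }
  }
  list(durations = durations, arrivals = arrivals)
}

# random rough discrete path crossing both wells, for property tests
random_walk_path <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n, 0, 0.45))
  x <- x - mean(x)
  tibble::tibble(time = seq_len(n) * 0.1, position = x)
}

# standard error of a time-average from contiguous block means
block_se <- function(x, n_blocks = 20) {
  blk <- cut(seq_along(x), breaks = n_blocks, labels = FALSE)
  means <- tapply(x, blk, mean)
  stats::sd(means) / sqrt(n_blocks)
}
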