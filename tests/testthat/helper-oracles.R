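# Independent reference implementations used as oracles. These are written
# with explicit per-epoch scanning loops, deliberately different in
# mechanism from the vectorized package code they check.

# Reference non-wear scan: zero-run bookkeeping by forward/backward passes,
# spike absorption and window test by explicit while-loops.
choi_reference <- function(counts, window = 90, spike = 2, flank = 30) {
  n <- length(counts)
  nz <- counts != 0
  left <- integer(n); right <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (nz[i]) 0L else run + 1L
    left[i] <- run
  }
  run <- 0L
  for (i in rev(seq_len(n))) {
    run <- if (nz[i]) 0L else run + 1L
    right[i] <- run
  }
  zerolike <- !nz
  i <- 1L
  while (i <= n) {
    if (nz[i]) {
      j <- i
      while (j < n && nz[j + 1L]) j <- j + 1L
      len <- j - i + 1L
      okL <- i > 1L && left[i - 1L] >= flank
      okR <- j < n && right[j + 1L] >= flank
      if (len <= spike && okL && okR) zerolike[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  nonwear <- logical(n)
  i <- 1L
  while (i <= n) {
    if (zerolike[i]) {
      j <- i
      while (j < n && zerolike[j + 1L]) j <- j + 1L
      if (j - i + 1L >= window) nonwear[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  !nonwear
}

# Brute-force windowed sums for epoch aggregation.
windowed_sum_reference <- function(x, r) {
  m <- length(x) %/% r
  out <- numeric(m)
  for (k in seq_len(m)) {
    s <- 0
    for (j in seq_len(r)) s <- s + x[(k - 1) * r + j]
    out[k] <- s
  }
  out
}

# Count maximal runs of >= min_len TRUEs by explicit scanning.
bout_reference <- function(active, min_len = 10) {
  n <- length(active)
  count <- 0L
  i <- 1L
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j < n && active[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) count <- count + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

# ICC(2,1) through R's two-way ANOVA table rather than closed-form sums.
icc_aov_reference <- function(x, y) {
  n <- length(x)
  df <- data.frame(val = c(x, y), subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(val ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Random one-day count sequence built from labelled blocks (activity, zero
# runs of varied length, short spikes) so that non-wear boundary cases are
# well represented.
random_day_counts <- function(n = 960) {
  counts <- integer(0)
  while (length(counts) < n) {
    type <- sample(c("activity", "zeros", "spike"), 1,
                   prob = c(0.35, 0.45, 0.2))
    block <- switch(type,
      activity = sample(1:800, sample(5:120, 1), replace = TRUE),
      zeros = integer(sample(c(1:40, 60:200), 1)),
      spike = sample(1:300, sample(1:4, 1), replace = TRUE)
    )
    counts <- c(counts, block)
  }
  counts[seq_len(n)]
}
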