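# Independent oracles used across tests. These deliberately re-derive the
# quantities by the slowest, most transparent route (per-droplet loops,
# exhaustive split search) so they share no code with the implementation.

# Exhaustive 1-D two-means: try every split of the sorted values, score by
# within-cluster sum of squares, return the best split's cluster means.
oracle_two_means <- function(x) {
  x <- sort(x)
  n <- length(x)
  best_ss <- Inf
  best_split <- 1L
  for (i in seq_len(n - 1L)) {
    left <- x[1:i]
    right <- x[(i + 1):n]
    ss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_split <- i
    }
  }
  list(mean_lo = mean(x[1:best_split]),
       mean_hi = mean(x[(best_split + 1):n]),
       within_ss = best_ss,
       total_ss = sum((x - mean(x))^2))
}

# Per-droplet loop classification (the reference for the vectorized path).
oracle_classify_loop <- function(ch1, ch2, cut1, cut2) {
  n_ch1 <- 0L; n_ch2 <- 0L; n_double <- 0L; n_neg <- 0L
  for (i in seq_along(ch1)) {
    p1 <- ch1[i] > cut1
    p2 <- ch2[i] > cut2
    if (p1) n_ch1 <- n_ch1 + 1L
    if (p2) n_ch2 <- n_ch2 + 1L
    if (p1 && p2) n_double <- n_double + 1L
    if (!p1 && !p2) n_neg <- n_neg + 1L
  }
  list(n_ch1_pos = n_ch1, n_ch2_pos = n_ch2,
       n_double_pos = n_double, n_neg = n_neg)
}

# Brute-force enumeration of the calling rules for a given fetus-specific
# count, assuming a passing NTC and adequate maternal signal.
oracle_call_rules <- function(fsp, ntc_max = 4L, min_pos = 5L, halfwidth = 2L) {
  verdict <- if (fsp >= min_pos) {
    "positive"
  } else if (fsp <= ntc_max) {
    "negative"
  } else {
    "inconclusive"
  }
  list(verdict = verdict,
       repeat_zone = fsp >= (min_pos - halfwidth) & fsp <= (min_pos + halfwidth))
}

# A small two-cloud amplitude table with known composition.
make_test_table <- function(n_neg, n_pos_ch1, n_pos_ch2, n_double = 0L,
                            seed = 1) {
  set.seed(seed)
  mk <- function(pos1, pos2) {
    data.frame(
      ch1_amplitude = ifelse(pos1, rnorm(length(pos1), 8000, 400),
                             rnorm(length(pos1), 1000, 150)),
      ch2_amplitude = ifelse(pos2, rnorm(length(pos2), 8000, 400),
                             rnorm(length(pos2), 1000, 150))
    )
  }
  p1 <- c(rep(FALSE, n_neg), rep(TRUE, n_pos_ch1), rep(FALSE, n_pos_ch2),
          rep(TRUE, n_double))
  p2 <- c(rep(FALSE, n_neg), rep(FALSE, n_pos_ch1), rep(TRUE, n_pos_ch2),
          rep(TRUE, n_double))
  mk(p1, p2)
}
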