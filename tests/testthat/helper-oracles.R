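# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by brute force / closed form, separate from the
# package's own code paths.

# Exhaustive modularity optimum: enumerate all set partitions of n nodes
# (restricted-growth strings) and maximize the unnormalized Q by direct
# summation. Feasible for n <= 10.
oracle_best_partition <- function(K, gamma = 1) {
  n <- nrow(K)
  A <- pmax(unname(K), 0); diag(A) <- 0
  k <- rowSums(A)
  B <- A - gamma * outer(k, k) / sum(A)   # Q = sum of B over same-module pairs
  diag(B) <- 0
  best_q <- -Inf; best <- NULL
  a <- integer(n)  # restricted growth string, 0-based
  recurse <- function(i, mx) {
    if (i > n) {
      same <- outer(a, a, "==")
      q <- sum(B[same])
      if (q > best_q) { best_q <<- q; best <<- a + 1L }
      return(invisible())
    }
    for (v in 0:mx) {
      a[i] <<- v
      recurse(i + 1, max(mx, v + 1))
    }
  }
  recurse(1, 0)
  list(Q = best_q, assignment = best)
}

# Direct double-loop modularity (independent of modularity_q's vectorized
# form).
oracle_modularity <- function(K, assignment, gamma = 1) {
  A <- pmax(unname(K), 0); diag(A) <- 0
  k <- rowSums(A); tw <- sum(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (i != j && assignment[i] == assignment[j]) {
      q <- q + A[i, j] - gamma * k[i] * k[j] / tw
    }
  }
  q
}

# ARI from a printed contingency table (closed form).
oracle_ari_from_table <- function(tab) {
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sij <- sum(comb2(tab)); sa <- sum(comb2(rowSums(tab)))
  sb <- sum(comb2(colSums(tab)))
  e <- sa * sb / comb2(n)
  ((sij - e) / ((sa + sb) / 2 - e))
}

# Dense Morlet band power (full-length IFFT per wavelet), the oracle the
# package's zoomed transform is checked against.
oracle_dense_morlet_power <- function(x, fs, freqs, n_cycles = 6) {
  nw <- length(x); X <- stats::fft(x)
  fax <- (seq_len(nw) - 1) * fs / nw
  pos <- fax <= fs / 2
  vapply(freqs, function(f) {
    st <- n_cycles / (2 * pi * f)
    G <- ifelse(pos, exp(-((fax - f)^2) * (2 * pi^2 * st^2)), 0)
    abs(stats::fft(X * G, inverse = TRUE) / nw)^2
  }, numeric(nw))
}

# Gaussian conditional mean from a KNOWN covariance (closed form).
oracle_conditional_mean <- function(Sigma, y_obs, obs_idx) {
  u <- setdiff(seq_len(nrow(Sigma)), obs_idx)
  Sigma[u, obs_idx, drop = FALSE] %*%
    solve(Sigma[obs_idx, obs_idx]) %*% y_obs
}

# Pearson kurtosis by direct formula.
oracle_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

# Two-channel matrix with an exact sample correlation r.
channels_with_correlation <- function(r, n = 2048, seed = 1) {
  set.seed(seed)
  a <- as.numeric(scale(rnorm(n)))
  b <- as.numeric(scale(rnorm(n)))
  b <- as.numeric(scale(b - a * sum(a * b) / sum(a * a)))  # exactly orthogonal
  rbind(a, r * a + sqrt(1 - r^2) * b)
}
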