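# Independent oracles: literal loop transcriptions of the defining formulas,
# written without reference to the package implementations.

# Approximate entropy, naive O(N^2 m): hard Chebyshev matches, self-match
# included, natural log.
apen_naive <- function(u, m, r) {
  phi <- function(mm) {
    np <- length(u) - mm + 1
    logc <- numeric(np)
    for (i in seq_len(np)) {
      cnt <- 0
      for (j in seq_len(np)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(u[i + k] - u[j + k]))
        if (d <= r) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / np)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

# Fuzzy entropy, naive: baseline-removed patterns, exponential membership
# exp(-d^n / r), self-match excluded, both phi averaged over N - m patterns.
fuzen_naive <- function(u, m, n, r) {
  phi <- function(mm, n_use) {
    sims <- numeric(n_use)
    for (i in seq_len(n_use)) {
      xi <- u[i:(i + mm - 1)] - mean(u[i:(i + mm - 1)])
      acc <- 0
      for (j in seq_len(n_use)) {
        if (j == i) next
        xj <- u[j:(j + mm - 1)] - mean(u[j:(j + mm - 1)])
        d <- max(abs(xi - xj))
        acc <- acc + exp(-(d^n) / r)
      }
      sims[i] <- acc / (n_use - 1)
    }
    mean(sims)
  }
  n_use <- length(u) - m
  log(phi(m, n_use)) - log(phi(m + 1, n_use))
}

# Population SD from the textbook formula.
sd_pop_naive <- function(u) sqrt(sum((u - sum(u) / length(u))^2) / length(u))

# Fully chaotic logistic map trajectory (x -> 4x(1-x)); its Lyapunov
# exponent is ln 2 per iteration.
logistic_series <- function(n, x0 = 0.4) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Brute-force FNN fraction at one dimension (Euclidean, Kennel criteria),
# used to cross-check select_dim_fnn's internals on tiny inputs.
fnn_fraction_naive <- function(u, m, tau, rtol = 15, atol = 2) {
  n <- length(u)
  M <- n - m * tau
  emb <- function(i, mm) u[i + (0:(mm - 1)) * tau]
  sd_u <- sd_pop_naive(u)
  false_ct <- 0
  for (i in seq_len(M)) {
    best <- Inf; nn <- NA
    for (j in seq_len(M)) {
      if (j == i) next
      d <- sqrt(sum((emb(i, m) - emb(j, m))^2))
      if (d < best) { best <- d; nn <- j }
    }
    extra <- abs(u[i + m * tau] - u[nn + m * tau])
    eps <- 1e-8 * sd_u
    f1 <- if (best > eps) extra / best > rtol else extra > eps
    f2 <- sqrt(best^2 + extra^2) / sd_u > atol
    if (f1 || f2) false_ct <- false_ct + 1
  }
  false_ct / M
}

# Small synthetic recording table wrapper used across tests.
tiny_dataset <- function(n_participants = 2, n_sessions = 2, n_points = 2,
                         seed = 101, ...) {
  generate_dataset(synth_config(n_participants = n_participants,
                                n_sessions = n_sessions,
                                n_points = n_points, seed = seed, ...))
}
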