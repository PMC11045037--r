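# Independent oracles shared across tests. None of these call the package's
# solver/agent code paths they are used to check.

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
}

# closed-form rate-distortion function of a uniform binary source under
# Hamming distortion: R(D) = ln 2 - H_b(D) for D <= 1/2
binary_rd_oracle <- function(D) log(2) - binary_entropy(pmin(D, 0.5))

# P(arm i attains the max) for independent normal beliefs, by 1-D adaptive
# quadrature of  integral phi((x - mu_i)/sd_i) prod_{j != i} Phi((x - mu_j)/sd_j) dx
normal_prob_optimal_oracle <- function(mu, sd = rep(1, length(mu))) {
  k <- length(mu)
  vapply(seq_len(k), function(i) {
    f <- function(x) {
      dens <- stats::dnorm(x, mu[i], sd[i])
      for (j in seq_len(k)[-i]) dens <- dens * stats::pnorm(x, mu[j], sd[j])
      dens
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# exact probability-matching distribution of a finite belief: weighted
# argmax frequencies with uniform tie splitting
enumerate_ts_probs <- function(atoms, weights = NULL) {
  atoms <- as.matrix(atoms)
  if (is.null(weights)) weights <- rep(1 / nrow(atoms), nrow(atoms))
  p <- numeric(ncol(atoms))
  for (z in seq_len(nrow(atoms))) {
    set <- which(atoms[z, ] == max(atoms[z, ]))
    p[set] <- p[set] + weights[z] / length(set)
  }
  p
}

# direct double-sum mutual information (nats)
mi_brute_force <- function(w, channel) {
  q <- drop(w %*% channel)
  total <- 0
  for (z in seq_along(w)) {
    for (a in seq_along(q)) {
      p <- channel[z, a]
      if (p > 0) total <- total + w[z] * p * log(p / q[a])
    }
  }
  total
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# two-stage draw of Algorithm-style probability matching from a fixed
# channel: uniform atom, then that atom's row
two_stage_draws <- function(channel, n) {
  z <- nrow(channel)
  k <- ncol(channel)
  zi <- sample.int(z, n, replace = TRUE)
  vapply(zi, function(i) sample.int(k, 1L, prob = channel[i, ]), integer(1))
}

expect_binomial_match <- function(freq, prob, n, label = "arm") {
  se <- sqrt(pmax(prob * (1 - prob), 1e-12) / n)
  expect_true(all(abs(freq - prob) <= 3 * se + 1e-12),
              label = sprintf("%s frequencies within 3-sigma of target", label))
}
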