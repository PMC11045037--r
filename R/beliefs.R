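#' Beta-Bernoulli arm posterior
#'
#' Independent Beta(alpha, beta) beliefs over the mean reward of each arm of
#' a Bernoulli bandit. `beta_posterior(1, 1, n_arms = k)` is the flat prior
#' used throughout the simulations.
#'
#' @param alpha,beta positive shape parameters; scalars are recycled to
#'   `n_arms`.
#' @param n_arms number of arms (defaults to the parameter length).
#' @return an object of class `c("beta_posterior", "arm_posterior")`.
#' @examples
#' p <- beta_posterior(1, 1, n_arms = 10)
#' p <- update_posterior(p, action = 3, reward = 1)
#' p$alpha
#' @export
beta_posterior <- function(alpha = 1, beta = 1, n_arms = NULL) {
  if (is.null(n_arms)) n_arms <- max(length(alpha), length(beta))
  alpha <- rep_len(as.numeric(alpha), n_arms)
  beta <- rep_len(as.numeric(beta), n_arms)
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("Beta parameters must be positive and finite")
  }
  structure(list(alpha = alpha, beta = beta, n_arms = n_arms),
            class = c("beta_posterior", "arm_posterior"))
}

#' Gaussian arm posterior with known reward noise
#'
#' Independent Normal(mu, var) beliefs over each arm's mean reward, with a
#' known reward noise variance shared across arms. The conjugate update is
#' precision-weighted averaging of prior mean and observed reward.
#'
#' @param mu prior/posterior means; scalars recycled to `n_arms`.
#' @param var positive belief variances; scalars recycled.
#' @param noise_var known reward noise variance (default 1, matching
#'   unit-variance Gaussian rewards).
#' @param n_arms number of arms (defaults to parameter length).
#' @return an object of class `c("gaussian_posterior", "arm_posterior")`.
#' @export
gaussian_posterior <- function(mu = 0, var = 1, noise_var = 1, n_arms = NULL) {
  if (is.null(n_arms)) n_arms <- max(length(mu), length(var))
  mu <- rep_len(as.numeric(mu), n_arms)
  var <- rep_len(as.numeric(var), n_arms)
  noise_var <- as.numeric(noise_var)
  if (any(!is.finite(mu)) || any(!is.finite(var)) || any(var <= 0)) {
    stop("`mu` must be finite and `var` positive")
  }
  if (length(noise_var) != 1L || !is.finite(noise_var) || noise_var <= 0) {
    stop("`noise_var` must be a single positive number")
  }
  structure(list(mu = mu, var = var, noise_var = noise_var, n_arms = n_arms),
            class = c("gaussian_posterior", "arm_posterior"))
}

#' Discrete posterior over explicit environment hypotheses
#'
#' A finitely supported belief: a matrix of arm-mean vectors (one hypothesis
#' per row) with associated weights. Used for frozen Monte-Carlo atom sets
#' and for exact enumeration in tests; it has no conjugate update.
#'
#' @param atoms numeric matrix, one environment hypothesis (arm-mean vector)
#'   per row.
#' @param weights probability vector over rows (default uniform).
#' @return an object of class `c("discrete_posterior", "arm_posterior")`.
#' @export
discrete_posterior <- function(atoms, weights = NULL) {
  atoms <- as.matrix(atoms)
  z <- nrow(atoms)
  if (z < 1L || anyNA(atoms)) stop("`atoms` must be a nonempty numeric matrix")
  if (is.null(weights)) weights <- rep(1 / z, z)
  weights <- as.numeric(weights)
  if (length(weights) != z || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    stop("`weights` must be a probability vector with one entry per atom")
  }
  structure(list(atoms = atoms, weights = weights, n_arms = ncol(atoms)),
            class = c("discrete_posterior", "arm_posterior"))
}

#' Number of arms of a posterior
#' @param posterior an `arm_posterior`.
#' @return integer arm count.
#' @export
n_arms <- function(posterior) {
  stopifnot(inherits(posterior, "arm_posterior"))
  posterior$n_arms
}

#' Conjugate posterior update from one observation
#'
#' Returns a new posterior of the same kind in which only the observed arm's
#' parameters change. Beta: a success increments alpha, a failure increments
#' beta. Gaussian with known noise variance v: the new variance is
#' `1 / (1/var + 1/v)` and the new mean is the precision-weighted average
#' `new_var * (mu/var + reward/v)`.
#'
#' @param posterior a [beta_posterior()] or [gaussian_posterior()].
#' @param action observed arm (1-based index).
#' @param reward observed reward; must be 0 or 1 for the Beta case.
#' @return updated posterior of the same class.
#' @export
update_posterior <- function(posterior, action, reward) {
  UseMethod("update_posterior")
}

#' @export
update_posterior.beta_posterior <- function(posterior, action, reward) {
  action <- as.integer(action)
  if (action < 1L || action > posterior$n_arms) stop("`action` out of range")
  if (!(reward %in% c(0, 1))) {
    stop("Beta-Bernoulli update requires a binary reward")
  }
  if (reward == 1) {
    posterior$alpha[action] <- posterior$alpha[action] + 1
  } else {
    posterior$beta[action] <- posterior$beta[action] + 1
  }
  posterior
}

#' @export
update_posterior.gaussian_posterior <- function(posterior, action, reward) {
  action <- as.integer(action)
  if (action < 1L || action > posterior$n_arms) stop("`action` out of range")
  v <- posterior$noise_var
  new_var <- 1 / (1 / posterior$var[action] + 1 / v)
  posterior$mu[action] <- new_var * (posterior$mu[action] /
                                       posterior$var[action] + reward / v)
  posterior$var[action] <- new_var
  posterior
}

#' @export
update_posterior.discrete_posterior <- function(posterior, action, reward) {
  stop("discrete posteriors are frozen hypothesis sets and cannot be updated")
}

#' Sample environment hypotheses from a posterior
#'
#' Draws `z` independent arm-mean vectors (arms independent under the
#' posterior). Each draw is one atom of an empirical belief source with
#' weight `1/z`; this is the Monte-Carlo discretization consumed by the
#' rate-distortion solver.
#'
#' @param posterior an `arm_posterior`.
#' @param z number of Monte-Carlo draws (>= 1).
#' @return `z` x `n_arms` numeric matrix, one hypothesis per row.
#' @export
sample_environments <- function(posterior, z) {
  UseMethod("sample_environments")
}

check_z <- function(z) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L) stop("`z` must be >= 1")
  z
}

#' @export
sample_environments.beta_posterior <- function(posterior, z) {
  z <- check_z(z)
  k <- posterior$n_arms
  matrix(stats::rbeta(z * k, rep(posterior$alpha, each = z),
                      rep(posterior$beta, each = z)), nrow = z, ncol = k)
}

#' @export
sample_environments.gaussian_posterior <- function(posterior, z) {
  z <- check_z(z)
  k <- posterior$n_arms
  matrix(stats::rnorm(z * k, mean = rep(posterior$mu, each = z),
                      sd = rep(sqrt(posterior$var), each = z)),
         nrow = z, ncol = k)
}

#' @export
sample_environments.discrete_posterior <- function(posterior, z) {
  z <- check_z(z)
  idx <- sample.int(nrow(posterior$atoms), z, replace = TRUE,
                    prob = posterior$weights)
  posterior$atoms[idx, , drop = FALSE]
}

#' Posterior mean reward per arm
#' @param posterior an `arm_posterior`.
#' @return numeric vector of posterior mean rewards.
#' @export
posterior_mean <- function(posterior) {
  UseMethod("posterior_mean")
}

#' @export
posterior_mean.beta_posterior <- function(posterior) {
  posterior$alpha / (posterior$alpha + posterior$beta)
}

#' @export
posterior_mean.gaussian_posterior <- function(posterior) {
  posterior$mu
}

#' @export
posterior_mean.discrete_posterior <- function(posterior) {
  drop(posterior$weights %*% posterior$atoms)
}

# Per-row argmax tie profile: indicator matrix of maxima divided by the
# number of maximizing arms in each row (uniform tie split).
argmax_profile <- function(samples) {
  mx <- samples[cbind(seq_len(nrow(samples)), max.col(samples, "first"))]
  ind <- samples == mx
  ind / rowSums(ind)
}

#' Posterior probability that each arm is optimal
#'
#' Monte-Carlo probability matching: the empirical frequency with which each
#' arm attains the maximum across `n` sampled mean vectors. Exact argmax ties
#' within a sample are split uniformly (relevant only for degenerate or
#' discrete posteriors; continuous posteriors tie with probability zero).
#' These are the Thompson Sampling action probabilities.
#'
#' @param posterior an `arm_posterior`.
#' @param n number of Monte-Carlo samples (default 10000).
#' @return probability vector over arms (sums to 1).
#' @export
prob_optimal <- function(posterior, n = 10000L) {
  n <- check_z(n)
  s <- sample_environments(posterior, n)
  colSums(argmax_profile(s)) / n
}

#' Entropy of the optimal action under a posterior
#'
#' Shannon entropy (nats) of the [prob_optimal()] vector. With k exchangeable
#' arms this is about `log(k)`; it shrinks towards zero as the posterior
#' concentrates, and it upper-bounds the rate of any rate-distortion-optimal
#' target-action channel built from the same beliefs.
#'
#' @inheritParams prob_optimal
#' @return nonnegative scalar, in nats.
#' @export
optimal_action_entropy <- function(posterior, n = 10000L) {
  shannon_entropy(prob_optimal(posterior, n))
}
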