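#' Ground-truth bandit environment
#'
#' An immutable value object describing a multi-armed bandit: one mean reward
#' per arm plus the reward family. All stochasticity in reward draws flows
#' through R's global RNG, so runs are reproducible from `set.seed()`.
#'
#' @param arm_means numeric vector of mean rewards, one per arm (reward
#'   units). Bernoulli bandits require every mean in \[0, 1\].
#' @param family reward family: `"bernoulli"` (rewards in \{0, 1\}) or
#'   `"gaussian"` (rewards with standard deviation `noise_sd`).
#' @param noise_sd positive reward standard deviation for the Gaussian family
#'   (default 1, i.e. unit-variance rewards); ignored for Bernoulli.
#'
#' @return an object of class `bandit_env` with fields `arm_means`, `family`,
#'   `noise_sd`, and `n_arms`.
#' @examples
#' env <- bandit_env(c(-1, 0, 1), family = "gaussian")
#' optimal_action(env)
#' action_gap(env)
#' @export
bandit_env <- function(arm_means, family = c("bernoulli", "gaussian"),
                       noise_sd = 1) {
  family <- match.arg(family)
  arm_means <- as.numeric(arm_means)
  if (length(arm_means) < 1L || anyNA(arm_means)) {
    stop("`arm_means` must be a nonempty numeric vector without NAs")
  }
  if (family == "bernoulli" && (any(arm_means < 0) || any(arm_means > 1))) {
    stop("bernoulli arm means must lie in [0, 1]")
  }
  noise_sd <- as.numeric(noise_sd)
  if (family == "gaussian" &&
      (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd <= 0)) {
    stop("gaussian `noise_sd` must be a single positive number")
  }
  structure(
    list(arm_means = arm_means, family = family, noise_sd = noise_sd,
         n_arms = length(arm_means)),
    class = "bandit_env"
  )
}

#' @export
print.bandit_env <- function(x, ...) {
  cat(sprintf("<bandit_env: %d-arm %s>\n", x$n_arms, x$family))
  cat("arm means:", paste(signif(x$arm_means, 4), collapse = " "), "\n")
  if (x$family == "gaussian") cat("noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Optimal action(s) of an environment
#'
#' Returns the full argmax set of the arm means together with a canonical
#' representative, the lowest index attaining the maximum.
#'
#' @param env a [bandit_env()].
#' @return list with `action` (canonical optimal arm, 1-based lowest index)
#'   and `set` (integer vector of all maximizing arms).
#' @export
optimal_action <- function(env) {
  stopifnot(inherits(env, "bandit_env"))
  set <- which(env$arm_means == max(env$arm_means))
  list(action = set[1L], set = set)
}

#' Action gap of an environment
#'
#' The difference between the highest and second-highest arm means. A
#' duplicated maximum gives a gap of zero. The gap controls how hard the
#' bandit is: capacity-limited agents concentrate less on the best arm as the
#' gap shrinks.
#'
#' @param env a [bandit_env()] with at least two arms.
#' @return nonnegative scalar.
#' @export
action_gap <- function(env) {
  stopifnot(inherits(env, "bandit_env"))
  if (env$n_arms < 2L) stop("gap undefined for a single-arm environment")
  s <- sort(env$arm_means, decreasing = TRUE)
  s[1L] - s[2L]
}

#' Sample rewards from an environment
#'
#' @param env a [bandit_env()].
#' @param action arm index (1-based).
#' @param n number of independent reward draws (default 1).
#' @return numeric vector of length `n`; Bernoulli rewards are in \{0, 1\}.
#' @export
sample_reward <- function(env, action, n = 1L) {
  stopifnot(inherits(env, "bandit_env"))
  action <- as.integer(action)
  if (length(action) != 1L || is.na(action) || action < 1L ||
      action > env$n_arms) {
    stop("`action` out of range")
  }
  m <- env$arm_means[action]
  switch(env$family,
    bernoulli = stats::rbinom(n, 1L, m),
    gaussian  = stats::rnorm(n, mean = m, sd = env$noise_sd)
  )
}

#' Expected (pseudo-)regret of an action
#'
#' The shortfall of the chosen arm's true mean relative to the best arm,
#' `max(arm_means) - arm_means[action]`. Zero exactly on the argmax set.
#' This is the per-period quantity accumulated by the regret curves, and the
#' base ingredient of the linear/squared regret distortions.
#'
#' @param env a [bandit_env()].
#' @param action arm index or vector of arm indices.
#' @return nonnegative numeric vector, one value per requested action.
#' @export
expected_regret <- function(env, action) {
  stopifnot(inherits(env, "bandit_env"))
  action <- as.integer(action)
  if (anyNA(action) || any(action < 1L) || any(action > env$n_arms)) {
    stop("`action` out of range")
  }
  max(env$arm_means) - env$arm_means[action]
}
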