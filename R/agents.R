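#' Agent configuration
#'
#' Bundles a decision rule and its hyperparameters for use by the experiment
#' harness. Supported kinds:
#' \describe{
#'   \item{`ts`}{Thompson Sampling: probability matching on the optimal
#'     action.}
#'   \item{`sts`}{Satisficing Thompson Sampling with slack `epsilon` (reward
#'     units): first arm whose regret under the sampled hypothesis is at
#'     most `epsilon`.}
#'   \item{`blasts`}{Blahut-Arimoto satisficing Thompson Sampling:
#'     probability matching on the rate-distortion-optimal target action.
#'     Parameterized by the information cost `lam` (reward units per nat) or
#'     equivalently the Lagrange multiplier `beta = 1/lam`; supply exactly
#'     one. `z` Monte-Carlo atoms discretize the posterior each period.}
#'   \item{`boltzmann`}{softmax over posterior mean rewards with temperature
#'     `alpha`.}
#'   \item{`uniform`}{uniform random arm (the zero-rate target).}
#'   \item{`oracle`}{plays the true optimal arm (debugging reference; zero
#'     regret by construction).}
#' }
#'
#' @param kind one of `"ts"`, `"sts"`, `"blasts"`, `"boltzmann"`,
#'   `"uniform"`, `"oracle"`.
#' @param epsilon satisficing slack for `sts`, >= 0.
#' @param lam information cost for `blasts`, in \[0, Inf\]. `lam = 0` is
#'   handled symbolically as exact TS, `lam = Inf` as the exact uniform rule;
#'   neither is passed to the solver.
#' @param beta alternative `blasts` parameterization, `beta = 1/lam`.
#' @param z Monte-Carlo atoms per `blasts` decision (default 1000, the
#'   sequential-run setting; one-shot action-distribution studies use more).
#' @param distortion distortion kind for `blasts` (default
#'   `"squared_regret"`).
#' @param alpha Boltzmann temperature, > 0.
#' @param tol,max_iter Blahut-Arimoto solver controls. The per-decision
#'   iteration budget defaults to 50 sweeps: a bounded agent spends a fixed
#'   computational effort per choice, and the finite-iteration behavior of
#'   the solver at extreme information costs (near-uniform action marginals
#'   when information is very expensive, annealing through Boltzmann-like
#'   distributions as the cost falls) is part of the decision rule. Raise
#'   `max_iter` for fully converged channels.
#' @return an object of class `bandit_agent`.
#' @examples
#' bandit_agent("blasts", lam = 0.1, z = 1000)
#' @export
bandit_agent <- function(kind = c("ts", "sts", "blasts", "boltzmann",
                                  "uniform", "oracle"),
                         epsilon = 0, lam = NULL, beta = NULL, z = 1000L,
                         distortion = c("squared_regret", "linear_regret"),
                         alpha = 1, tol = 1e-9, max_iter = 50L) {
  kind <- match.arg(kind)
  distortion <- match.arg(distortion)
  if (kind == "sts" && (!is.numeric(epsilon) || epsilon < 0)) {
    stop("`epsilon` must be >= 0")
  }
  if (kind == "blasts") {
    if (is.null(lam) == is.null(beta)) {
      stop("blasts requires exactly one of `lam` or `beta`")
    }
    if (is.null(lam)) {
      if (beta < 0) stop("`beta` must be >= 0")
      lam <- if (beta == 0) Inf else 1 / beta
    }
    if (lam < 0) stop("`lam` must be >= 0")
  }
  if (kind == "boltzmann" && (!is.numeric(alpha) || alpha <= 0)) {
    stop("`alpha` must be > 0")
  }
  z <- check_z(z)
  structure(list(kind = kind, epsilon = epsilon, lam = lam, z = z,
                 distortion = distortion, alpha = alpha, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "bandit_agent")
}

#' @export
print.bandit_agent <- function(x, ...) {
  extra <- switch(x$kind,
    sts = sprintf(" (epsilon = %g)", x$epsilon),
    blasts = sprintf(" (lambda = %g, Z = %d, %s)", x$lam, x$z, x$distortion),
    boltzmann = sprintf(" (alpha = %g)", x$alpha),
    "")
  cat(sprintf("<bandit_agent: %s%s>\n", x$kind, extra))
  invisible(x)
}

# uniform draw from the argmax set of a sampled mean vector
sample_argmax <- function(theta) {
  set <- which(theta == max(theta))
  if (length(set) == 1L) set else set[sample.int(length(set), 1L)]
}

#' Thompson Sampling action selection
#'
#' Draws one environment hypothesis from the posterior and returns an arm
#' drawn uniformly at random from that hypothesis's argmax set. Marginally
#' over the draw this implements probability matching: each arm is selected
#' with its posterior probability of being optimal.
#'
#' @param posterior an `arm_posterior`.
#' @return arm index (1-based).
#' @export
ts_select <- function(posterior) {
  theta <- drop(sample_environments(posterior, 1L))
  sample_argmax(theta)
}

#' Satisficing Thompson Sampling action selection
#'
#' Draws one hypothesis theta and settles for the first arm (lowest index)
#' whose regret under theta, `max(theta) - theta[a]`, is at most `epsilon`.
#' The set is never empty: theta's optimal arm has regret zero. With
#' `epsilon = 0` the rule reduces to Thompson Sampling up to tie handling
#' (min-index instead of a uniform tie draw).
#'
#' @param posterior an `arm_posterior`.
#' @param epsilon nonnegative satisficing slack (reward units).
#' @return arm index (1-based).
#' @export
sts_select <- function(posterior, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("`epsilon` must be a single nonnegative number")
  }
  theta <- drop(sample_environments(posterior, 1L))
  which((max(theta) - theta) <= epsilon)[1L]
}

#' Rate-distortion-optimal action distribution over frozen atoms
#'
#' Builds a uniform empirical source over the supplied hypotheses, the
#' requested regret distortion, and runs Blahut-Arimoto at `beta = 1/lam`.
#' This is the per-period core of BLASTS: the converged channel defines the
#' target action, and its mutual information is the period's rate.
#'
#' @param atoms numeric matrix of environment hypotheses (rows), e.g. from
#'   [sample_environments()].
#' @param lam positive finite information cost (reward units per nat); or
#'   supply `beta` instead.
#' @param beta alternative parameterization, `beta = 1/lam`.
#' @param distortion `"linear_regret"` or `"squared_regret"`.
#' @param tol,max_iter solver controls; `max_iter` defaults to the
#'   50-sweep per-decision budget of [bandit_agent()].
#' @return an `rd_solution` (see [blahut_arimoto()]); its `marginal` is the
#'   agent's action distribution and `rate` its cognitive load in nats.
#' @export
blasts_action_distribution <- function(atoms, lam = NULL, beta = NULL,
                                       distortion = c("linear_regret",
                                                      "squared_regret"),
                                       tol = 1e-9, max_iter = 50L) {
  distortion <- match.arg(distortion)
  if (is.null(lam) == is.null(beta)) {
    stop("supply exactly one of `lam` or `beta`")
  }
  if (is.null(beta)) {
    if (!is.finite(lam) || lam <= 0) {
      stop("`lam` must be in (0, Inf); the lam = 0 / Inf limits are handled ",
           "symbolically by blasts_select()")
    }
    beta <- 1 / lam
  }
  src <- discrete_source(atoms)
  d <- build_distortion(src$atoms, distortion)
  blahut_arimoto(src, d, beta, tol = tol, max_iter = max_iter)
}

#' BLASTS action selection
#'
#' The two-stage draw of Blahut-Arimoto satisficing Thompson Sampling:
#' sample `z` fresh hypotheses from the posterior, compute the
#' rate-distortion-optimal channel at cost `lam`, pick one of the atoms
#' uniformly, and sample an action from that atom's channel row. Marginally
#' this matches the channel's action marginal. The limits are exact:
#' `lam = 0` delegates to [ts_select()] and `lam = Inf` draws a uniform arm;
#' neither touches the solver.
#'
#' @param posterior an `arm_posterior`.
#' @param agent a [bandit_agent()] of kind `"blasts"` (or arguments matching
#'   one via `...`, e.g. `lam`, `z`).
#' @param ... overrides passed to [bandit_agent()] when `agent` is missing.
#' @return arm index (1-based), with the period's rate (nats) attached as
#'   attribute `"rate"` (NA in the symbolic limits).
#' @export
blasts_select <- function(posterior, agent = NULL, ...) {
  if (is.null(agent)) agent <- bandit_agent("blasts", ...)
  stopifnot(inherits(agent, "bandit_agent"), agent$kind == "blasts")
  k <- n_arms(posterior)
  if (agent$lam == 0) {
    return(structure(ts_select(posterior), rate = NA_real_))
  }
  if (is.infinite(agent$lam)) {
    return(structure(sample.int(k, 1L), rate = 0))
  }
  atoms <- sample_environments(posterior, agent$z)
  sol <- blasts_action_distribution(atoms, lam = agent$lam,
                                    distortion = agent$distortion,
                                    tol = agent$tol,
                                    max_iter = agent$max_iter)
  zi <- sample.int(nrow(atoms), 1L)
  a <- sample.int(k, 1L, prob = sol$channel[zi, ])
  structure(a, rate = sol$rate)
}

#' Boltzmann (softmax) action probabilities
#'
#' Probabilities proportional to `exp(means / alpha)` (log-sum-exp
#' stabilized). As `alpha -> 0` the rule greedily selects the highest mean;
#' as `alpha -> Inf` it tends to uniform. A point-estimate baseline that
#' ignores distributional information.
#'
#' @param means numeric vector of (point-estimate) mean rewards.
#' @param alpha positive temperature.
#' @return probability vector over arms.
#' @examples
#' boltzmann_prob(c(-1, 0, 1), alpha = 1)
#' @export
boltzmann_prob <- function(means, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  x <- means / alpha
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Uniform random action selection
#'
#' The zero-rate baseline: every arm with probability `1/num_arms`,
#' independent of beliefs, so the induced belief-to-action channel carries
#' no information about the environment.
#'
#' @param num_arms number of arms (>= 1).
#' @return arm index (1-based).
#' @export
uniform_select <- function(num_arms) {
  num_arms <- check_z(num_arms)
  sample.int(num_arms, 1L)
}
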