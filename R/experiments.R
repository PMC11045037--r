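#' Specify a sequential bandit experiment
#'
#' Bundles prior, agent, horizon, number of runs, and seeding for
#' [run_bandit()]. Each run draws a fresh ground-truth environment from the
#' agent's own prior (the Bayesian-regret setting behind the regret curves)
#' unless `fixed_env` pins one for debugging. The reward family is implied
#' by the prior: Beta beliefs pair with Bernoulli rewards, Gaussian beliefs
#' with Gaussian rewards whose noise variance equals the prior's
#' `noise_var`.
#'
#' @param prior a [beta_posterior()] or [gaussian_posterior()] (the agent's
#'   time-1 belief, and the environment-generating distribution).
#' @param agent a [bandit_agent()].
#' @param horizon number of periods T (>= 1).
#' @param runs number of independent simulation runs (>= 1).
#' @param seed base integer seed; run i uses three derived substreams
#'   (environment draw, agent decisions, diagnostics), so two specs sharing
#'   a seed see identical per-run environments (paired comparisons).
#' @param diagnostics if TRUE, record per-period rate (BLASTS) and a
#'   Monte-Carlo estimate of the optimal-action entropy of the current
#'   posterior. The diagnostic draws use their own RNG substream, so
#'   enabling them never perturbs decisions.
#' @param diag_samples Monte-Carlo samples for the entropy diagnostic
#'   (default 1000).
#' @param fixed_env optional [bandit_env()] used for every run instead of
#'   prior draws.
#' @return an object of class `bandit_experiment`.
#' @export
bandit_experiment <- function(prior, agent, horizon, runs = 1L, seed = 1L,
                              diagnostics = FALSE, diag_samples = 1000L,
                              fixed_env = NULL) {
  stopifnot(inherits(prior, "arm_posterior"), inherits(agent, "bandit_agent"))
  if (inherits(prior, "discrete_posterior")) {
    stop("sequential runs need an updatable prior (beta or gaussian)")
  }
  horizon <- as.integer(horizon)
  runs <- as.integer(runs)
  if (horizon < 1L) stop("`horizon` must be >= 1")
  if (runs < 1L) stop("`runs` must be >= 1")
  family <- if (inherits(prior, "beta_posterior")) "bernoulli" else "gaussian"
  if (!is.null(fixed_env)) {
    stopifnot(inherits(fixed_env, "bandit_env"))
    if (fixed_env$family != family) {
      stop(sprintf("prior implies %s rewards but `fixed_env` is %s",
                   family, fixed_env$family))
    }
    if (fixed_env$n_arms != prior$n_arms) {
      stop("`fixed_env` arm count does not match the prior")
    }
  }
  structure(list(prior = prior, agent = agent, horizon = horizon,
                 runs = runs, seed = as.integer(seed), family = family,
                 diagnostics = isTRUE(diagnostics),
                 diag_samples = as.integer(diag_samples),
                 fixed_env = fixed_env),
            class = "bandit_experiment")
}

#' @export
print.bandit_experiment <- function(x, ...) {
  cat(sprintf("<bandit_experiment: %s %d-arm, agent %s, T = %d, %d run(s), seed %d>\n",
              x$family, x$prior$n_arms, x$agent$kind, x$horizon, x$runs,
              x$seed))
  invisible(x)
}

# environment drawn from the agent's prior (means sampled from the belief)
draw_env_from_prior <- function(prior, family) {
  means <- drop(sample_environments(prior, 1L))
  if (family == "bernoulli") {
    bandit_env(means, family = "bernoulli")
  } else {
    bandit_env(means, family = "gaussian", noise_sd = sqrt(prior$noise_var))
  }
}

# lean per-period BLASTS step for sequential runs: fresh atoms, regret
# distortion, BA at beta = 1/lam, two-stage action draw, all inside one
# compiled kernel for conjugate posteriors. Skips the exact rate
# computation unless diagnostics ask for it.
blasts_step <- function(post, agent, want_rate) {
  sq <- agent$distortion == "squared_regret"
  if (inherits(post, "beta_posterior")) {
    ba_blasts_period(0L, post$alpha, post$beta, agent$z, 1 / agent$lam, sq,
                     agent$tol, agent$max_iter, want_rate)
  } else if (inherits(post, "gaussian_posterior")) {
    ba_blasts_period(1L, post$mu, sqrt(post$var), agent$z, 1 / agent$lam, sq,
                     agent$tol, agent$max_iter, want_rate)
  } else {
    z <- agent$z
    atoms <- sample_environments(post, z)
    res <- blasts_action_distribution(atoms, lam = agent$lam,
                                      distortion = agent$distortion,
                                      tol = agent$tol,
                                      max_iter = agent$max_iter)
    zi <- sample.int(z, 1L)
    list(action = sample.int(ncol(atoms), 1L, prob = res$channel[zi, ]),
         rate = res$rate)
  }
}

run_one <- function(spec, i) {
  env_seed <- spec$seed + 3L * i - 2L
  act_seed <- spec$seed + 3L * i - 1L
  diag_seed <- spec$seed + 3L * i
  set.seed(env_seed)
  env <- if (is.null(spec$fixed_env)) {
    draw_env_from_prior(spec$prior, spec$family)
  } else {
    spec$fixed_env
  }
  diag_state <- NULL
  if (spec$diagnostics) {
    set.seed(diag_seed)
    diag_state <- get(".Random.seed", envir = globalenv())
  }
  set.seed(act_seed)

  agent <- spec$agent
  horizon <- spec$horizon
  act <- integer(horizon)
  rew <- numeric(horizon)
  reg <- numeric(horizon)
  rate <- rep(NA_real_, horizon)
  ent <- rep(NA_real_, horizon)
  post <- spec$prior
  opt <- optimal_action(env)$action

  for (t in seq_len(horizon)) {
    if (spec$diagnostics) {
      main_state <- get(".Random.seed", envir = globalenv())
      assign(".Random.seed", diag_state, envir = globalenv())
      ent[t] <- optimal_action_entropy(post, n = spec$diag_samples)
      diag_state <- get(".Random.seed", envir = globalenv())
      assign(".Random.seed", main_state, envir = globalenv())
    }
    a <- switch(agent$kind,
      ts = ts_select(post),
      sts = sts_select(post, agent$epsilon),
      blasts = {
        if (agent$lam == 0) {
          ts_select(post)
        } else if (is.infinite(agent$lam)) {
          rate[t] <- 0
          sample.int(env$n_arms, 1L)
        } else {
          st <- blasts_step(post, agent, spec$diagnostics)
          rate[t] <- st$rate
          st$action
        }
      },
      boltzmann = {
        p <- boltzmann_prob(posterior_mean(post), agent$alpha)
        sample.int(length(p), 1L, prob = p)
      },
      uniform = uniform_select(env$n_arms),
      oracle = opt
    )
    r <- sample_reward(env, a)
    act[t] <- a
    rew[t] <- r
    reg[t] <- expected_regret(env, a)
    post <- update_posterior(post, a, r)
  }
  structure(
    data.frame(t = seq_len(horizon), action = act, reward = rew, regret = reg,
               rate_nats = rate, entropy_nats = ent),
    env = env, run = i, seed = spec$seed, class = c("trajectory",
                                                    "data.frame"))
}

#' Run a sequential bandit simulation
#'
#' For each run: draw a ground-truth environment from the prior, reset the
#' posterior to the prior, then loop over periods (agent selects, the
#' environment rewards, the posterior updates). Per-period regret is
#' pseudo-regret, the true-mean gap `max(arm_means) - arm_means[A_t]` of
#' the chosen arm, not the realized-reward shortfall. Fully reproducible:
#' the same spec (including seed) yields bit-identical trajectories.
#'
#' @param spec a [bandit_experiment()].
#' @return list of per-run trajectory data.frames (columns `t`, `action`,
#'   `reward`, `regret`, `rate_nats`, `entropy_nats`; the latter two are NA
#'   unless recorded), each carrying its environment as attribute `env`.
#' @examples
#' spec <- bandit_experiment(beta_posterior(1, 1, n_arms = 3),
#'                           bandit_agent("ts"), horizon = 50, runs = 2)
#' trajs <- run_bandit(spec)
#' aggregate_regret(trajs)[50, ]
#' @export
run_bandit <- function(spec) {
  stopifnot(inherits(spec, "bandit_experiment"))
  out <- lapply(seq_len(spec$runs), function(i) run_one(spec, i))
  attr(out, "spec") <- spec
  out
}

traj_matrix <- function(trajectories, col) {
  lens <- vapply(trajectories, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("trajectories must have equal length")
  vapply(trajectories, function(tr) tr[[col]], numeric(lens[1]))
}

#' Average cumulative regret across runs
#'
#' @param trajectories list of trajectories from [run_bandit()].
#' @return data.frame of class `regret_summary` with columns `t`,
#'   `mean_cum_regret`, `se` (standard error across runs).
#' @export
aggregate_regret <- function(trajectories) {
  reg <- traj_matrix(trajectories, "regret")
  cum <- apply(reg, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  n <- ncol(cum)
  m <- rowMeans(cum)
  se <- if (n > 1L) apply(cum, 1L, stats::sd) / sqrt(n) else rep(0, nrow(cum))
  structure(data.frame(t = seq_len(nrow(cum)), mean_cum_regret = m, se = se),
            class = c("regret_summary", "data.frame"))
}

#' @export
plot.regret_summary <- function(x, ...) {
  plot(x$t, x$mean_cum_regret, type = "l",
       xlab = "period t", ylab = "mean cumulative regret", ...)
  invisible(x)
}

#' Per-period rate curve of a BLASTS agent, with TS entropy reference
#'
#' Runs the experiment with diagnostics enabled and averages the per-period
#' rate of the BLASTS channel across runs, together with the agent's
#' own concurrent optimal-action entropy estimate. A companion Thompson
#' Sampling run under the same seed (hence identical per-run environments)
#' supplies the reference entropy trajectory of an unconstrained learner.
#'
#' @param spec a [bandit_experiment()] whose agent has kind `"blasts"`.
#' @return data.frame with columns `t`, `mean_rate_nats` (BLASTS channel
#'   rate), `mean_entropy_nats` (entropy of the BLASTS agent's own
#'   posterior), `mean_entropy_ts` (TS companion).
#' @export
rate_curve <- function(spec) {
  stopifnot(inherits(spec, "bandit_experiment"))
  if (spec$agent$kind != "blasts") {
    stop("rate diagnostics are defined for blasts agents")
  }
  spec$diagnostics <- TRUE
  trajs <- run_bandit(spec)
  ts_spec <- spec
  ts_spec$agent <- bandit_agent("ts")
  ts_trajs <- run_bandit(ts_spec)
  data.frame(
    t = seq_len(spec$horizon),
    mean_rate_nats = rowMeans(traj_matrix(trajs, "rate_nats")),
    mean_entropy_nats = rowMeans(traj_matrix(trajs, "entropy_nats")),
    mean_entropy_ts = rowMeans(traj_matrix(ts_trajs, "entropy_nats"))
  )
}

#' Rate-distortion trade-off table: BLASTS versus satisficing TS
#'
#' On one shared set of `z` hypotheses drawn from the prior, tabulates the
#' operating points of (a) BLASTS channels across a beta grid and (b) the
#' deterministic satisficing map `theta -> first arm with regret <= epsilon`
#' across an epsilon grid. Both are scored on the same empirical source with
#' both regret distortions, so the table exposes the trade-off each rule
#' achieves between rate and expected regret. BLASTS solves the
#' rate-distortion problem for this source, so at matched distortion its
#' rate is never above the satisficing rule's.
#'
#' @param prior an `arm_posterior` (beliefs at the period under study).
#' @param z number of shared Monte-Carlo atoms.
#' @param beta_grid BLASTS Lagrange multipliers.
#' @param epsilon_grid satisficing slacks (reward units).
#' @param distortion distortion kind the BLASTS solver optimizes (default
#'   `"squared_regret"`).
#' @param tol,max_iter solver controls.
#' @return data.frame with columns `method` ("blasts"/"sts"), `parameter`
#'   (beta or epsilon), `rate_nats`, `expected_linear_regret`,
#'   `expected_squared_regret`.
#' @export
rd_tradeoff_table <- function(prior, z, beta_grid, epsilon_grid,
                              distortion = c("squared_regret",
                                             "linear_regret"),
                              tol = 1e-9, max_iter = 10000L) {
  distortion <- match.arg(distortion)
  if (length(beta_grid) < 1L || length(epsilon_grid) < 1L) {
    stop("grids must be nonempty")
  }
  atoms <- sample_environments(prior, z)
  src <- discrete_source(atoms)
  d_lin <- build_distortion(atoms, "linear_regret")
  d_sq <- build_distortion(atoms, "squared_regret")
  d_solve <- if (distortion == "linear_regret") d_lin else d_sq
  score <- function(channel) {
    w <- src$weights
    c(rate = mutual_information(src, channel),
      lin = sum(w * rowSums(channel * d_lin)),
      sq = sum(w * rowSums(channel * d_sq)))
  }
  bl <- lapply(beta_grid, function(b) {
    sol <- blahut_arimoto(src, d_solve, b, tol = tol, max_iter = max_iter)
    s <- score(sol$channel)
    data.frame(method = "blasts", parameter = b, rate_nats = s[["rate"]],
               expected_linear_regret = s[["lin"]],
               expected_squared_regret = s[["sq"]])
  })
  k <- ncol(atoms)
  st <- lapply(epsilon_grid, function(eps) {
    a_eps <- max.col((d_lin <= eps) * 1, "first")  # first arm w/ regret <= eps
    channel <- matrix(0, nrow(atoms), k)
    channel[cbind(seq_len(nrow(atoms)), a_eps)] <- 1
    s <- score(channel)
    data.frame(method = "sts", parameter = eps, rate_nats = s[["rate"]],
               expected_linear_regret = s[["lin"]],
               expected_squared_regret = s[["sq"]])
  })
  out <- do.call(rbind, c(bl, st))
  rownames(out) <- NULL
  out
}

#' Action-distribution sweep over the information cost
#'
#' Evaluates the BLASTS action marginal and rate on one frozen atom set
#' across a grid of information costs, so comparisons across lambda are
#' paired. The limits are handled symbolically: `lambda = 0` is the exact
#' probability-matching (TS) channel (uniform over each atom's argmax set)
#' and `lambda = Inf` is the uniform rule at rate zero.
#'
#' @param posterior an `arm_posterior` to discretize (ignored when `atoms`
#'   is supplied).
#' @param lam_grid vector of information costs in \[0, Inf\].
#' @param z Monte-Carlo atoms (default 50000, the one-shot study setting).
#' @param distortion distortion kind (default `"linear_regret"`, under which
#'   lambda has reward-per-nat units).
#' @param atoms optional pre-drawn hypothesis matrix (overrides
#'   `posterior`/`z`).
#' @param tol,max_iter solver controls; defaults to the per-decision budget
#'   of [bandit_agent()] since the sweep characterizes agent behavior.
#' @return data.frame with columns `lambda`, `rate_nats`, and one
#'   `p_arm<i>` column per arm holding the marginal action probabilities.
#' @export
lambda_sweep <- function(posterior = NULL, lam_grid, z = 50000L,
                         distortion = c("linear_regret", "squared_regret"),
                         atoms = NULL, tol = 1e-9, max_iter = 50L) {
  distortion <- match.arg(distortion)
  if (length(lam_grid) < 1L) stop("`lam_grid` must be nonempty")
  if (is.null(atoms)) {
    if (is.null(posterior)) stop("supply `posterior` or `atoms`")
    atoms <- sample_environments(posterior, z)
  }
  atoms <- as.matrix(atoms)
  src <- discrete_source(atoms)
  k <- ncol(atoms)
  rows <- lapply(lam_grid, function(lam) {
    if (lam == 0) {
      channel <- argmax_profile(atoms)
      marg <- marginal_action(src, channel)
      rate <- mutual_information(src, channel)
    } else if (is.infinite(lam)) {
      marg <- rep(1 / k, k)
      rate <- 0
    } else {
      sol <- blasts_action_distribution(atoms, lam = lam,
                                        distortion = distortion, tol = tol,
                                        max_iter = max_iter)
      marg <- sol$marginal
      rate <- sol$rate
    }
    out <- data.frame(lambda = lam, rate_nats = rate)
    out[paste0("p_arm", seq_len(k))] <- as.list(marg)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample complexity of a learning target from a rate series
#'
#' Counts the periods whose recorded rate exceeds `tol_nats`, a Monte-Carlo
#' surrogate for the number of periods with strictly positive epistemic
#' uncertainty about the target. The uniform target (`lambda = Inf`) has
#' rate identically zero and hence sample complexity zero; cheaper targets
#' stop demanding information earlier.
#'
#' @param rates numeric vector of per-period rates (nats); NAs are ignored.
#' @param tol_nats positive threshold below which a rate counts as zero
#'   (default 1e-3; an exact `rate > 0` test is meaningless under
#'   Monte-Carlo noise).
#' @return integer count of information-demanding periods.
#' @export
sample_complexity <- function(rates, tol_nats = 1e-3) {
  if (!is.numeric(tol_nats) || tol_nats <= 0) stop("`tol_nats` must be > 0")
  sum(rates > tol_nats, na.rm = TRUE)
}
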