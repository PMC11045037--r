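#' Build a prior from a config block
#'
#' `{"kind": "beta", "alpha": 1, "beta": 1, "n_arms": 10}` or
#' `{"kind": "gaussian", "mu": 0, "var": 1, "noise_var": 1, "n_arms": 10}`.
#' Scalar parameters are recycled across arms; vectors give per-arm values.
#'
#' @param cfg named list parsed from JSON.
#' @return an `arm_posterior`.
#' @export
build_prior <- function(cfg) {
  kind <- cfg$kind
  if (is.null(kind)) stop("prior block needs a `kind`")
  switch(kind,
    beta = beta_posterior(alpha = cfg$alpha %||% 1, beta = cfg$beta %||% 1,
                          n_arms = cfg$n_arms),
    gaussian = gaussian_posterior(mu = cfg$mu %||% 0, var = cfg$var %||% 1,
                                  noise_var = cfg$noise_var %||% 1,
                                  n_arms = cfg$n_arms),
    stop(sprintf("unknown prior kind '%s'", kind))
  )
}

#' Build an agent from a config block
#'
#' e.g. `{"kind": "blasts", "lam": 0.1, "Z": 1000,
#' "distortion": "squared_regret"}`. Accepts `Z` or `z`, and `lam` or
#' `beta` (exactly one for blasts); `"lam": "Inf"` is understood.
#'
#' @param cfg named list parsed from JSON.
#' @return a [bandit_agent()].
#' @export
build_agent <- function(cfg) {
  if (is.null(cfg$kind)) stop("agent block needs a `kind`")
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  bandit_agent(kind = cfg$kind,
               epsilon = cfg$epsilon %||% 0,
               lam = num(cfg$lam),
               beta = num(cfg$beta),
               z = cfg$Z %||% cfg$z %||% 1000L,
               distortion = cfg$distortion %||% "squared_regret",
               alpha = cfg$alpha %||% 1,
               tol = cfg$tol %||% 1e-9,
               max_iter = cfg$max_iter %||% 10000L)
}

#' Build an explicit environment from a config block
#'
#' e.g. `{"family": "gaussian", "arm_means": [-1, 0, 1], "noise_sd": 1.0}`.
#'
#' @param cfg named list parsed from JSON.
#' @return a [bandit_env()].
#' @export
build_env <- function(cfg) {
  if (is.null(cfg$arm_means)) stop("environment block needs `arm_means`")
  bandit_env(unlist(cfg$arm_means), family = cfg$family %||% "gaussian",
             noise_sd = cfg$noise_sd %||% 1)
}

#' Read a JSON experiment configuration
#'
#' Parses a config file with blocks `prior`, `agent`, and scalars `horizon`,
#' `runs`, `seed`, `diagnostics`, `diag_samples`, plus an optional inline
#' `environment` used for every run. Returns a ready-to-run
#' [bandit_experiment()]; the raw parsed config is attached as attribute
#' `"config"` for provenance sidecars.
#'
#' @param path path to a JSON file.
#' @param seed optional override of the config's seed (CLI `--seed`).
#' @return a [bandit_experiment()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$prior) || is.null(cfg$agent)) {
    stop("config must contain `prior` and `agent` blocks")
  }
  spec <- bandit_experiment(
    prior = build_prior(cfg$prior),
    agent = build_agent(cfg$agent),
    horizon = cfg$horizon %||% 1000L,
    runs = cfg$runs %||% 1L,
    seed = seed %||% cfg$seed %||% 1L,
    diagnostics = cfg$diagnostics %||% FALSE,
    diag_samples = cfg$diag_samples %||% 1000L,
    fixed_env = if (!is.null(cfg$environment)) build_env(cfg$environment)
  )
  attr(spec, "config") <- cfg
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
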