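#' Discrete belief source
#'
#' An empirical distribution over environment hypotheses: a matrix of
#' arm-mean vectors (atoms, one per row) with a probability weight per atom
#' (default uniform `1/Z`). This is the information source compressed by the
#' rate-distortion solver.
#'
#' @param atoms numeric matrix of hypotheses, one arm-mean vector per row.
#' @param weights probability vector over atoms; default uniform.
#' @return an object of class `discrete_source` with fields `atoms`,
#'   `weights`, `n_atoms`, `n_arms`.
#' @export
discrete_source <- function(atoms, weights = NULL) {
  atoms <- as.matrix(atoms)
  z <- nrow(atoms)
  if (z < 1L || anyNA(atoms)) stop("`atoms` must be a nonempty numeric matrix")
  if (is.null(weights)) weights <- rep(1 / z, z)
  weights <- as.numeric(weights)
  if (length(weights) != z) stop("one weight per atom required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("`weights` must be nonnegative and sum to 1")
  }
  structure(list(atoms = atoms, weights = weights, n_atoms = z,
                 n_arms = ncol(atoms)),
            class = "discrete_source")
}

#' Shannon entropy of a probability vector
#'
#' `-sum(p * log(p))` in nats, with the convention `0 * log(0) = 0`. The
#' result lies in `[0, log(length(p))]`.
#'
#' @param p probability vector (nonnegative, sums to 1 within 1e-9; small
#'   drift is renormalized silently).
#' @return nonnegative scalar, in nats.
#' @examples
#' shannon_entropy(rep(1 / 3, 3)) # log(3)
#' @export
shannon_entropy <- function(p) {
  p <- check_prob(p, what = "p")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

# Validate (and silently renormalize) a probability vector. Entries below
# 1e-300 are treated as exact zeros so that log terms never underflow to NaN.
check_prob <- function(p, tol = 1e-9, what = "probability vector") {
  p <- as.numeric(p)
  if (length(p) < 1L || anyNA(p)) stop(sprintf("`%s` must be numeric", what))
  if (any(p < 0)) stop(sprintf("`%s` has negative entries", what))
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("`%s` sums to %.12g, not 1", what, s))
  }
  p <- p / s
  p[p < 1e-300] <- 0
  p
}

# Validate a row-stochastic channel matrix; rows with drift up to 1e-9 are
# renormalized, anything larger is an error (numerical noise vs. a bug).
check_channel <- function(channel, n_atoms = NULL, n_arms = NULL) {
  channel <- as.matrix(channel)
  if (anyNA(channel) || any(channel < 0)) {
    stop("channel entries must be nonnegative")
  }
  if (!is.null(n_atoms) && nrow(channel) != n_atoms) {
    stop("channel must have one row per source atom")
  }
  if (!is.null(n_arms) && ncol(channel) != n_arms) {
    stop("channel must have one column per arm")
  }
  rs <- rowSums(channel)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("channel rows must each sum to 1 (within 1e-9)")
  }
  channel / rs
}

#' Marginal action distribution of a source-channel pair
#'
#' `q(a) = sum_theta w(theta) * delta(a | theta)`: the action distribution an
#' agent exhibits when the environment is first drawn from the source and an
#' action is then drawn from the channel row of that hypothesis.
#'
#' @param source a [discrete_source()].
#' @param channel row-stochastic matrix with one row per atom and one column
#'   per arm.
#' @return probability vector over arms.
#' @export
marginal_action <- function(source, channel) {
  stopifnot(inherits(source, "discrete_source"))
  channel <- check_channel(channel, source$n_atoms, source$n_arms)
  drop(source$weights %*% channel)
}

#' Mutual information between source and channel output (rate)
#'
#' `I(E; A) = sum_theta w(theta) sum_a delta(a|theta) log(delta(a|theta) /
#' q(a))` in nats, with `q` the marginal action distribution. This is the
#' rate of the channel: the number of nats about the environment carried by
#' the action distribution, the framework's measure of cognitive load. It
#' equals the decomposition `H(q) - sum_theta w(theta) H(row_theta)`
#' (total minus aleatoric uncertainty) and satisfies
#' `0 <= I <= min(H(w), H(q))`.
#'
#' @inheritParams marginal_action
#' @return nonnegative scalar, in nats.
#' @export
mutual_information <- function(source, channel) {
  stopifnot(inherits(source, "discrete_source"))
  channel <- check_channel(channel, source$n_atoms, source$n_arms)
  q <- drop(source$weights %*% channel)
  logq <- ifelse(q > 0, log(q), 0)
  lr <- channel * (log(pmax(channel, 1e-300)) -
                     matrix(logq, nrow(channel), ncol(channel), byrow = TRUE))
  lr[channel <= 0] <- 0
  max(0, sum(source$weights * rowSums(lr)))
}
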