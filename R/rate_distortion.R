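#' Build a regret distortion matrix from environment hypotheses
#'
#' For each hypothesis theta (row of `atoms`) and arm a, the distortion is
#' the regret of playing a if theta were reality:
#' `linear_regret`: `d(a, theta) = max(theta) - theta[a]`;
#' `squared_regret`: its square. Every row has a zero at that hypothesis's
#' optimal arm(s). Squared regret is the distortion under which the
#' rate-distortion-optimal target action carries a Bayesian regret
#' guarantee; linear regret makes the Lagrange multiplier interpretable as a
#' cost of information in reward units per nat.
#'
#' @param atoms numeric matrix of arm-mean vectors, one hypothesis per row,
#'   or a [discrete_source()].
#' @param kind `"linear_regret"` or `"squared_regret"`.
#' @return an object of class `distortion_matrix`: the numeric matrix with a
#'   `kind` attribute.
#' @examples
#' build_distortion(rbind(c(-1, 0, 1)), "linear_regret") # row (2, 1, 0)
#' @export
build_distortion <- function(atoms, kind = c("linear_regret",
                                             "squared_regret")) {
  kind <- match.arg(kind)
  if (inherits(atoms, "discrete_source")) atoms <- atoms$atoms
  atoms <- as.matrix(atoms)
  if (nrow(atoms) < 1L || anyNA(atoms)) {
    stop("`atoms` must be a nonempty numeric matrix (equal arm counts)")
  }
  mx <- atoms[cbind(seq_len(nrow(atoms)), max.col(atoms, "first"))]
  d <- mx - atoms
  if (kind == "squared_regret") d <- d * d
  structure(d, kind = kind, class = c("distortion_matrix", class(d)))
}

#' Blahut-Arimoto solver for the rate-distortion problem
#'
#' Computes the channel `delta(a | theta)` minimizing the Lagrangian
#' `I(source; A) + beta * E[d]` over row-stochastic channels, by the classic
#' alternating updates: `q(a) <- sum_theta w(theta) delta(a|theta)` then
#' `delta(a|theta) <- q(a) exp(-beta d(a, theta)) / normalizer`. Since the
#' channel is a deterministic function of the marginal, the iteration state
#' is `q` alone; the solver starts from the uniform channel and stops when
#' the L1 drift of `q` between sweeps falls below `tol` or `max_iter` is
#' hit. Boltzmann factors are log-sum-exp stabilized by the per-row
#' distortion minimum; arms whose marginal underflows to zero are dropped
#' implicitly (they cannot revive under the multiplicative update). Small `beta` prioritizes rate minimization (cheap,
#' uninformed behavior); large `beta` prioritizes distortion minimization
#' and concentrates each row on its distortion-minimizing arms.
#'
#' @param source a [discrete_source()].
#' @param d distortion matrix (atoms x arms, nonnegative), e.g. from
#'   [build_distortion()].
#' @param beta nonnegative, finite Lagrange multiplier on distortion.
#' @param tol convergence tolerance on the marginal's L1 drift per sweep
#'   (default 1e-9).
#' @param max_iter iteration cap (default 10000); if reached, the solution is
#'   returned with `converged = FALSE`.
#' @return an object of class `rd_solution`: list with `channel`, `marginal`,
#'   `rate` (nats, equal to the channel's mutual information), `beta`,
#'   `expected_distortion`, `iterations`, `converged`, and the per-sweep
#'   `lagrangian` trace (the alternating-minimization objective
#'   `I + beta E[d]`, nonincreasing).
#' @examples
#' src <- discrete_source(rbind(c(0, 1), c(1, 0)))
#' d <- build_distortion(src, "linear_regret")
#' blahut_arimoto(src, d, beta = 2)$rate
#' @export
blahut_arimoto <- function(source, d, beta, tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(source, "discrete_source"))
  d <- as.matrix(d)
  if (nrow(d) != source$n_atoms || ncol(d) != source$n_arms) {
    stop("distortion matrix must be atoms x arms")
  }
  if (anyNA(d) || any(d < 0)) stop("distortion entries must be nonnegative")
  if (length(beta) != 1L || is.na(beta) || beta < 0 || !is.finite(beta)) {
    stop("`beta` must be a single finite nonnegative number")
  }
  if (tol <= 0) stop("`tol` must be positive")
  res <- ba_solve(source$weights, d, beta, tol, as.integer(max_iter), TRUE, TRUE)
  res$beta <- beta
  res$source <- source
  class(res) <- "rd_solution"
  res
}

#' @export
print.rd_solution <- function(x, ...) {
  cat(sprintf(
    "<rd_solution: beta = %g, rate = %.6g nats, E[d] = %.6g, %d iter%s>\n",
    x$beta, x$rate, x$expected_distortion, x$iterations,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Trace a rate-distortion curve over a beta grid
#'
#' Runs [blahut_arimoto()] at each multiplier in `beta_grid` and tabulates
#' the operating points. Along the sweep the rate is nondecreasing and the
#' expected distortion nonincreasing in beta, so the table can be read as
#' either the rate-distortion function R(D) or, inverted at a rate budget,
#' the distortion-rate function D(R).
#'
#' @inheritParams blahut_arimoto
#' @param beta_grid nonempty vector of nonnegative multipliers.
#' @return data.frame with columns `beta`, `lambda` (= 1/beta), `rate_nats`,
#'   `expected_distortion`, `iterations`, `converged`.
#' @export
rd_curve <- function(source, d, beta_grid, tol = 1e-9, max_iter = 10000L) {
  if (length(beta_grid) < 1L) stop("`beta_grid` must be nonempty")
  rows <- lapply(beta_grid, function(b) {
    s <- blahut_arimoto(source, d, b, tol = tol, max_iter = max_iter)
    data.frame(beta = b, lambda = 1 / b, rate_nats = s$rate,
               expected_distortion = s$expected_distortion,
               iterations = s$iterations, converged = s$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rd_curve", class(out))
  out
}

#' @export
plot.rd_curve <- function(x, ...) {
  plot(x$expected_distortion, x$rate_nats, type = "b", pch = 16,
       xlab = "expected distortion", ylab = "rate (nats)", ...)
  invisible(x)
}
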