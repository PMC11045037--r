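test_that("Thompson Sampling probability-matches a finite belief", {
  degen <- discrete_posterior(rbind(c(0.2, 0.8)))
  expect_true(all(replicate(50, ts_select(degen)) == 2L))

  set.seed(41)
  two <- discrete_posterior(rbind(c(1, 0), c(0, 1)))
  n <- 10000
  f <- tabulate(replicate(n, ts_select(two)), 2) / n
  expect_binomial_match(f, c(0.5, 0.5), n)

  tie <- discrete_posterior(rbind(c(0.5, 0.5)))
  f <- tabulate(replicate(n, ts_select(tie)), 2) / n
  expect_binomial_match(f, c(0.5, 0.5), n)

  # weighted atoms with a tie atom: exact enumeration oracle
  atoms <- rbind(c(0.9, 0.1, 0.1), c(0.1, 0.8, 0.2), c(0.3, 0.6, 0.6))
  w <- c(0.5, 0.3, 0.2)
  post <- discrete_posterior(atoms, w)
  f <- tabulate(replicate(n, ts_select(post)), 3) / n
  expect_binomial_match(f, enumerate_ts_probs(atoms, w), n)
})

test_that("satisficing TS settles for the first good-enough arm", {
  forced <- discrete_posterior(rbind(c(-1, 0, 1)))
  expect_equal(sts_select(forced, epsilon = 1), 2L)   # regrets (2, 1, 0)
  expect_equal(sts_select(forced, epsilon = 0), 3L)
  expect_equal(sts_select(forced, epsilon = 10), 1L)  # min-index rule
  expect_error(sts_select(forced, epsilon = -0.1), "nonnegative")

  # P(arm 1) is nondecreasing in epsilon
  set.seed(43)
  post <- gaussian_posterior(mu = c(0, 0.5), var = 1)
  p1 <- vapply(c(0, 0.5, 1, 2, 8), function(eps) {
    mean(replicate(3000, sts_select(post, eps)) == 1L)
  }, numeric(1))
  expect_true(all(diff(p1) >= -0.03))
  expect_equal(p1[5], 1)
})

test_that("the BLASTS channel behaves across the information-cost range", {
  set.seed(45)
  # single atom: no information to transmit; small lam exploits its best arm
  one <- rbind(c(0.1, 0.9, 0.4))
  s <- blasts_action_distribution(one, lam = 1e-3)
  expect_equal(s$rate, 0, tolerance = 1e-9)
  expect_gt(s$marginal[2], 0.999)
  expect_error(blasts_action_distribution(one, lam = 0), "symbolically")
  expect_error(blasts_action_distribution(one), "exactly one")

  # the two-stage draw marginalizes to the computed action marginal
  atoms <- sample_environments(gaussian_posterior(c(-0.5, 0, 0.5), 1), 300)
  sol <- blasts_action_distribution(atoms, lam = 0.3)
  n <- 10000
  f <- tabulate(two_stage_draws(sol$channel, n), 3) / n
  expect_binomial_match(f, sol$marginal, n)
})

test_that("BLASTS selection limits are exact TS and exact uniform", {
  post <- gaussian_posterior(mu = c(-1, 0, 1), var = 1)
  set.seed(47)
  a1 <- replicate(200, blasts_select(post, bandit_agent("blasts", lam = 0)))
  set.seed(47)
  a2 <- replicate(200, ts_select(post))
  expect_identical(as.integer(a1), as.integer(a2))

  set.seed(48)
  ag <- bandit_agent("blasts", lam = Inf)
  draws <- replicate(6000, blasts_select(post, ag))
  expect_equal(attr(blasts_select(post, ag), "rate"), 0)
  f <- tabulate(as.integer(draws), 3) / 6000
  expect_binomial_match(f, rep(1 / 3, 3), 6000)
})

test_that("BLASTS is sensitive to the action gap and to belief uncertainty", {
  set.seed(49)
  eps <- matrix(rnorm(5000 * 3), 5000)
  # action gap: raise the middle arm toward the best; P(best) cannot grow
  p_best <- vapply(c(-1, -0.5, 0, 0.5, 1), function(m) {
    atoms <- sweep(eps, 2, c(-1, m, 1), "+")
    blasts_action_distribution(atoms, lam = 1)$marginal[3]
  }, numeric(1))
  expect_true(all(diff(p_best) <= 0.02))
  expect_gt(p_best[1], 0.9)

  # uncertainty: wider beliefs flatten the action distribution
  p_max <- vapply(c(0.5, 1, 2, 4), function(s) {
    atoms <- sweep(eps * s, 2, c(-1, 0, 1), "+")
    max(blasts_action_distribution(atoms, lam = 1)$marginal)
  }, numeric(1))
  expect_true(all(diff(p_max) <= 0.02))
})

test_that("Boltzmann probabilities follow the softmax with its limits", {
  expect_equal(boltzmann_prob(c(-1, 0, 1), 1),
               exp(c(-1, 0, 1)) / sum(exp(c(-1, 0, 1))), tolerance = 1e-12)
  expect_equal(boltzmann_prob(c(-1, 0, 1), 1)[3], 0.66524096, tolerance = 1e-6)
  expect_gt(boltzmann_prob(c(-1, 0, 1), 1e-6)[3], 1 - 1e-9)
  expect_equal(boltzmann_prob(c(-1, 0, 1), 1e6), rep(1 / 3, 3),
               tolerance = 1e-5)
  expect_equal(boltzmann_prob(c(1000, 2000), 1), c(0, 1))  # stabilized
  expect_error(boltzmann_prob(c(0, 1), 0), "positive")
})

test_that("the uniform rule is belief-free with a zero-rate channel", {
  set.seed(51)
  n <- 30000
  f <- tabulate(replicate(n, uniform_select(3)), 3) / n
  expect_binomial_match(f, rep(1 / 3, 3), n)
  expect_equal(uniform_select(1), 1L)

  src <- discrete_source(matrix(rnorm(12), 4))
  flat <- matrix(1 / 3, 4, 3)
  expect_equal(mutual_information(src, flat), 0)
})
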