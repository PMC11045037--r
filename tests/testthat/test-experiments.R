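test_that("experiment specs validate their pieces", {
  prior <- beta_posterior(1, 1, n_arms = 3)
  expect_error(bandit_experiment(discrete_posterior(rbind(c(0, 1))),
                                 bandit_agent("ts"), 10), "updatable")
  expect_error(bandit_experiment(prior, bandit_agent("ts"), 0), ">= 1")
  expect_error(
    bandit_experiment(prior, bandit_agent("ts"), 10,
                      fixed_env = bandit_env(c(-1, 0, 1), "gaussian")),
    "bernoulli")
  expect_error(
    bandit_experiment(prior, bandit_agent("ts"), 10,
                      fixed_env = bandit_env(c(0.1, 0.9), "bernoulli")),
    "arm count")
})

test_that("an oracle agent incurs exactly zero regret", {
  spec <- bandit_experiment(beta_posterior(1, 1, n_arms = 5),
                            bandit_agent("oracle"), horizon = 100, runs = 3)
  trajs <- run_bandit(spec)
  expect_true(all(vapply(trajs, function(x) all(x$regret == 0), logical(1))))
  agg <- aggregate_regret(trajs)
  expect_true(all(agg$mean_cum_regret == 0))
})

test_that("a uniform agent's cumulative regret matches the mean gap", {
  env <- bandit_env(c(-1, 0, 1), family = "gaussian")
  spec <- bandit_experiment(gaussian_posterior(0, 1, n_arms = 3),
                            bandit_agent("uniform"), horizon = 300,
                            runs = 200, seed = 2, fixed_env = env)
  agg <- aggregate_regret(run_bandit(spec))
  final <- agg[300, ]
  # per-period regret is uniform on (2, 1, 0): mean 1, variance 2/3
  expect_lt(abs(final$mean_cum_regret - 300), 3 * sqrt(300 * 2 / 3 / 200))
  expect_lt(abs(final$mean_cum_regret - 300), 3.5 * final$se)
})

test_that("Thompson Sampling regret is sublinear", {
  spec <- bandit_experiment(beta_posterior(1, 1, n_arms = 10),
                            bandit_agent("ts"), horizon = 2000, runs = 60,
                            seed = 3)
  reg <- sapply(run_bandit(spec), function(x) x$regret)
  per_period <- rowMeans(reg)
  early <- mean(per_period[1:200])
  late <- mean(per_period[1801:2000])
  expect_lt(late, 0.25 * early)
})

test_that("runs are bit-identical under a fixed seed and diagnostics never perturb decisions", {
  prior <- beta_posterior(1, 1, n_arms = 4)
  spec <- bandit_experiment(prior, bandit_agent("blasts", lam = 1, z = 100),
                            horizon = 40, runs = 2, seed = 9)
  t1 <- run_bandit(spec)
  t2 <- run_bandit(spec)
  expect_identical(t1[[1]]$action, t2[[1]]$action)
  expect_identical(t1[[2]]$reward, t2[[2]]$reward)

  spec_diag <- spec
  spec_diag$diagnostics <- TRUE
  t3 <- run_bandit(spec_diag)
  expect_identical(t1[[1]]$action, t3[[1]]$action)
  expect_identical(t1[[2]]$action, t3[[2]]$action)
  expect_true(all(is.finite(t3[[1]]$entropy_nats)))
  expect_true(all(is.finite(t3[[1]]$rate_nats)))
})

test_that("two specs sharing a seed face identical environments (paired runs)", {
  prior <- beta_posterior(1, 1, n_arms = 6)
  e1 <- run_bandit(bandit_experiment(prior, bandit_agent("ts"),
                                     horizon = 5, runs = 3, seed = 11))
  e2 <- run_bandit(bandit_experiment(prior, bandit_agent("uniform"),
                                     horizon = 5, runs = 3, seed = 11))
  for (i in 1:3) {
    expect_identical(attr(e1[[i]], "env")$arm_means,
                     attr(e2[[i]], "env")$arm_means)
  }
})

test_that("aggregate_regret averages running sums with standard errors", {
  fake <- function(reg) data.frame(t = seq_along(reg), action = 1L,
                                   reward = 0, regret = reg,
                                   rate_nats = NA_real_,
                                   entropy_nats = NA_real_)
  agg <- aggregate_regret(list(fake(rep(1, 5)), fake(rep(1, 5))))
  expect_equal(agg$mean_cum_regret, 1:5)
  expect_equal(agg$se, rep(0, 5))
  expect_error(aggregate_regret(list(fake(rep(1, 5)), fake(rep(1, 4)))),
               "equal length")
})

test_that("first-period choices under an exchangeable prior are uniform", {
  spec <- bandit_experiment(beta_posterior(1, 1, n_arms = 5),
                            bandit_agent("ts"), horizon = 1, runs = 2000,
                            seed = 13)
  first <- vapply(run_bandit(spec), function(x) x$action[1], integer(1))
  expect_gt(stats::chisq.test(tabulate(first, 5))$p.value, 0.001)
})

test_that("rate curves stay below the concurrent optimal-action entropy", {
  prior <- beta_posterior(1, 1, n_arms = 5)
  spec <- bandit_experiment(prior, bandit_agent("blasts", beta = 10, z = 300),
                            horizon = 30, runs = 4, seed = 15,
                            diag_samples = 2000)
  rc <- rate_curve(spec)
  expect_equal(nrow(rc), 30)
  expect_lt(abs(rc$mean_entropy_nats[1] - log(5)), 0.05)
  expect_true(all(rc$mean_rate_nats <= rc$mean_entropy_nats + 0.05))
  expect_error(rate_curve(bandit_experiment(prior, bandit_agent("ts"), 5)),
               "blasts")
})

test_that("the BLASTS/STS trade-off table has the advertised anchor points", {
  prior <- beta_posterior(1, 1, n_arms = 8)
  set.seed(17)
  tab <- rd_tradeoff_table(prior, z = 400,
                           beta_grid = c(0.5, 5, 50, 5000),
                           epsilon_grid = c(0, 0.2, 2))
  set.seed(17)
  shared_atoms <- sample_environments(prior, 400)
  bl <- tab[tab$method == "blasts", ]
  st <- tab[tab$method == "sts", ]
  # both extreme-fidelity rules achieve (near) zero distortion
  expect_lt(bl$expected_squared_regret[4], 1e-4)
  expect_lt(st$expected_squared_regret[1], 1e-12)
  # a slack larger than any achievable regret pins arm 1 at zero rate
  expect_equal(st$rate_nats[3], 0)
  expect_equal(st$expected_linear_regret[3],
               mean(build_distortion(shared_atoms, "linear_regret")[, 1]),
               tolerance = 1e-9)
})

test_that("lambda sweeps interpolate between probability matching and uniform", {
  set.seed(19)
  post <- gaussian_posterior(mu = c(-1, 0, 1), var = 1)
  atoms <- sample_environments(post, 4000)
  sw <- lambda_sweep(atoms = atoms, lam_grid = c(0, 0.05, 0.5, 5, 500, Inf))
  expect_true(all(diff(sw$rate_nats) <= 1e-6))
  expect_equal(unlist(sw[1, 3:5], use.names = FALSE),
               enumerate_ts_probs(atoms), tolerance = 1e-9)
  expect_equal(unlist(sw[6, 3:5], use.names = FALSE), rep(1 / 3, 3))
  expect_equal(sw$rate_nats[6], 0)
})

test_that("sample complexity counts information-demanding periods", {
  expect_equal(sample_complexity(c(0.5, 0.2, 0.0001), tol_nats = 0.001), 2L)
  expect_equal(sample_complexity(rep(0, 10)), 0L)
  expect_equal(sample_complexity(c(NA, 0.5, NA)), 1L)
  expect_error(sample_complexity(1, tol_nats = 0), "> 0")

  spec <- bandit_experiment(beta_posterior(1, 1, n_arms = 3),
                            bandit_agent("blasts", lam = Inf),
                            horizon = 50, runs = 1, seed = 21,
                            diagnostics = TRUE)
  tr <- run_bandit(spec)[[1]]
  expect_equal(sample_complexity(tr$rate_nats), 0L)
})
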