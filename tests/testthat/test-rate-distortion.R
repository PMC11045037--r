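test_that("regret distortion rows are gaps with zero minima", {
  expect_equal(unclass(build_distortion(rbind(c(-1, 0, 1)), "linear_regret")),
               rbind(c(2, 1, 0)), ignore_attr = TRUE)
  expect_equal(unclass(build_distortion(rbind(c(-1, 0, 1)), "squared_regret")),
               rbind(c(4, 1, 0)), ignore_attr = TRUE)
  expect_equal(unclass(build_distortion(rbind(c(0.2, 0.8)), "linear_regret")),
               rbind(c(0.6, 0)), ignore_attr = TRUE)
  d <- build_distortion(matrix(rnorm(40), 10), "squared_regret")
  expect_true(all(apply(d, 1, min) == 0))
  expect_error(build_distortion(matrix(c(1, NA), 1)), "numeric matrix")
})

test_that("Blahut-Arimoto limits: beta = 0 washes out, huge beta exploits", {
  src <- discrete_source(rbind(c(-1, 0, 1), c(1, 0, -1)))
  d <- build_distortion(src, "linear_regret")
  s0 <- blahut_arimoto(src, d, 0)
  expect_equal(s0$rate, 0)
  expect_true(all(abs(s0$channel - 1 / 3) < 1e-12))

  sb <- blahut_arimoto(src, d, 1e6)
  expect_equal(sb$expected_distortion, 0, tolerance = 1e-12)
  expect_equal(sb$channel, rbind(c(0, 0, 1), c(1, 0, 0)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(blahut_arimoto(src, d, -1), "nonnegative")
})

test_that("binary Hamming solutions sit on the closed-form R(D) curve", {
  src <- discrete_source(rbind(c(1, 0), c(0, 1)))
  d <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  for (b in seq(0.1, 10, length.out = 8)) {
    s <- blahut_arimoto(src, d, b)
    expect_true(s$converged)
    expect_lt(abs(s$rate - binary_rd_oracle(s$expected_distortion)), 1e-4)
  }
})

test_that("solution invariants: rate is the channel's mutual information and the objective never increases", {
  set.seed(31)
  for (rep in 1:8) {
    z <- sample(3:20, 1); k <- sample(2:6, 1)
    src <- discrete_source(matrix(runif(z * k), z),
                           as.numeric(prop.table(runif(z))))
    d <- build_distortion(src, sample(c("linear_regret", "squared_regret"), 1))
    s <- blahut_arimoto(src, d, runif(1, 0.1, 20))
    expect_equal(s$rate, mutual_information(src, s$channel), tolerance = 1e-9)
    expect_equal(s$expected_distortion,
                 sum(src$weights * rowSums(s$channel * d)), tolerance = 1e-9)
    expect_true(all(diff(s$lagrangian) <= 1e-12))
    expect_true(all(abs(rowSums(s$channel) - 1) < 1e-9))
  }
})

test_that("solutions are invariant to atom permutation and weight-split duplication", {
  set.seed(33)
  z <- 6; k <- 4
  atoms <- matrix(runif(z * k), z)
  w <- as.numeric(prop.table(runif(z)))
  d <- build_distortion(atoms, "linear_regret")
  s <- blahut_arimoto(discrete_source(atoms, w), d, 3)

  perm <- sample(z)
  sp <- blahut_arimoto(discrete_source(atoms[perm, ], w[perm]),
                       build_distortion(atoms[perm, ], "linear_regret"), 3)
  expect_equal(sp$rate, s$rate, tolerance = 1e-9)
  expect_equal(sp$marginal, s$marginal, tolerance = 1e-9)

  w2 <- c(w[1] / 2, w[1] / 2, w[-1])
  sd2 <- blahut_arimoto(
    discrete_source(atoms[c(1, 1:z), ], w2),
    build_distortion(atoms[c(1, 1:z), ], "linear_regret"), 3)
  expect_equal(sd2$rate, s$rate, tolerance = 1e-9)
  expect_equal(sd2$expected_distortion, s$expected_distortion,
               tolerance = 1e-9)
})

test_that("rd_curve is a monotone trade-off and degenerates correctly", {
  set.seed(35)
  src <- discrete_source(matrix(runif(60), 15))
  d <- build_distortion(src, "squared_regret")
  curve <- rd_curve(src, d, beta_grid = 10^seq(-1, 3, length.out = 10))
  expect_true(all(diff(curve$rate_nats) >= -1e-6))
  expect_true(all(diff(curve$expected_distortion) <= 1e-9))

  single <- rd_curve(discrete_source(rbind(c(0.1, 0.9))),
                     build_distortion(rbind(c(0.1, 0.9)), "linear_regret"),
                     beta_grid = c(0.5, 5, 50))
  expect_true(all(single$rate_nats == 0))

  one <- rd_curve(src, d, beta_grid = 0)
  expect_equal(one$rate_nats, 0)
})

test_that("an exhausted iteration cap is reported, not hidden", {
  src <- discrete_source(matrix(runif(40), 10))
  d <- build_distortion(src, "linear_regret")
  s <- blahut_arimoto(src, d, 2, tol = 1e-15, max_iter = 3)
  expect_false(s$converged)
  expect_equal(s$iterations, 3L)
})
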