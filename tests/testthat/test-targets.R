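# Target quantities and elicitation techniques.

test_that("quantile elicitation agrees with a sort-and-interpolate oracle", {
  set.seed(101)
  for (k in 1:1000) {
    S <- sample(2:40, 1)
    B <- sample(1:4, 1)
    p <- sort(runif(sample(1:4, 1), 0.05, 0.95))
    z <- rnorm(B * S, sd = sample(c(0.1, 1, 10), 1))
    q <- matrix(quantile_elicit(z, B, S, p), B, length(p))
    zm <- matrix(z, B, S)
    for (b in seq_len(B)) {
      oracle <- unname(quantile(zm[b, ], probs = p, type = 7))
      expect_equal(q[b, ], oracle, tolerance = 1e-12)
    }
    # monotone across p within every batch row
    expect_true(all(apply(q, 1, function(r) !is.unsorted(r))))
  }
})

test_that("quantile examples: median, quartiles, constants", {
  expect_equal(as.numeric(quantile_elicit(c(1, 2, 3, 4, 5), 1, 5, 0.5)), 3)
  expect_equal(as.numeric(quantile_elicit(c(1, 2, 3, 4, 5), 1, 5,
                                          c(0.25, 0.5, 0.75))), c(2, 3, 4))
  expect_equal(as.numeric(quantile_elicit(rep(7, 10), 1, 10,
                                          c(0.25, 0.5, 0.75))), c(7, 7, 7))
  expect_error(quantile_elicit(1:5, 1, 5, 1.5), "\\(0,1\\)")
})

test_that("moment elicitation uses the population divisor", {
  m <- moment_elicit(c(0, 2), B = 1, S = 2)
  expect_equal(as.numeric(m), c(1, 1), tolerance = 1e-6)  # sd with divisor S
  mc <- moment_elicit(rep(3, 8), B = 2, S = 4)
  expect_equal(matrix(mc, 2, 2)[, 1], c(3, 3))
  expect_equal(matrix(mc, 2, 2)[, 2], c(0, 0), tolerance = 1e-5)
})

test_that("histogram elicitation returns the sample multiset (optionally thinned)", {
  z <- c(1, 2, 3)
  expect_equal(histogram_elicit(z), z)
  zz <- rnorm(500)
  h <- histogram_elicit(zz, max_points = 100)
  expect_lte(length(h), 100)
  expect_true(all(h %in% zz))
  # identity feeds the discrepancy: MMD(z, z) = 0
  expect_equal(mmd2_biased(z, z, d = 1), 0)
})

test_that("r_squared matches hand computation and its invariances", {
  th <- matrix(c(0, 1), 1, 2)
  y <- matrix(c(0, 2), 1, 2)
  expect_equal(r_squared(th, y), 0.25)   # var 0.5 / var 2
  # y == theta => 1; constant theta => 0
  th2 <- matrix(rnorm(10), 2, 5)
  expect_equal(r_squared(th2, th2), c(1, 1), tolerance = 1e-12)
  expect_equal(r_squared(matrix(1, 2, 5), th2 + 5), c(0, 0))
  # shift invariance and joint scale invariance
  set.seed(8)
  th3 <- matrix(rnorm(20), 4, 5); y3 <- th3 + matrix(rnorm(20, sd = .5), 4, 5)
  base <- r_squared(th3, y3)
  expect_equal(r_squared(th3 + 3, y3 + 3), base, tolerance = 1e-10)
  expect_equal(r_squared(th3 * -2.5, y3 * -2.5), base, tolerance = 1e-10)
  expect_error(r_squared(matrix(1, 1, 1), matrix(1, 1, 1)), "two design rows")
})

test_that("compute_target covers parameter, prediction, groups, differences", {
  st <- study_definition("normal_linear")
  lam <- st$lambda_star
  set.seed(5)
  noise <- priormatch:::draw_base_noise(st$model, 3, 7)
  nat <- priormatch:::natural_duals(lam)
  draws <- priormatch:::sample_priors_dual(st$model$prior, nat, 3, 7,
                                           noise$prior)
  sim <- priormatch:::simulate_data_dual(st$model$likelihood, st$model$design,
                                         draws, noise$lik)
  n <- 21
  # parameter projection returns the draws unchanged
  zs <- compute_target(target_quantity("s", "parameter", parameter = "s"),
                       draws, sim, st$model$design)
  expect_equal(zs$v, draws$values$s$v)
  # identical groups difference is zero
  zd <- compute_target(target_quantity("d0", "group_difference",
                                       rows_a = c(1, 2), rows_b = c(1, 2)),
                       draws, sim, st$model$design)
  expect_equal(zd$v, rep(0, n), tolerance = 1e-12)
  # group mean equals the mean of the selected prediction columns
  zg <- compute_target(target_quantity("g", "group_mean", rows = c(1, 3)),
                       draws, sim, st$model$design)
  ym <- matrix(sim$y$v, n, 6)
  expect_equal(zg$v, rowMeans(ym[, c(1, 3)]))
  # marginal mean = unweighted mean of cell means (balanced cells here)
  zm <- compute_target(target_quantity("m", "marginal_mean",
                                       groups = list(1, 3)),
                       draws, sim, st$model$design)
  expect_equal(zm$v, zg$v, tolerance = 1e-12)
  expect_error(compute_target(target_quantity("b", "parameter",
                                              parameter = "nope"),
                              draws, sim, st$model$design), "unknown")
})

test_that("elicited statistics are deterministic given the simulated arrays", {
  z <- rnorm(60)
  a <- quantile_elicit(z, 3, 20); b <- quantile_elicit(z, 3, 20)
  expect_identical(a, b)
  expect_identical(moment_elicit(z, 3, 20), moment_elicit(z, 3, 20))
})

test_that("expected count at a design point matches the closed-form binomial mean", {
  # degenerate priors (sd ~ 0) around the study-2 truth: the relaxed count at
  # x = 0 should average 100 * plogis(-0.51) up to relaxation + MC error
  st <- study_definition("binomial")
  lam <- hyperparameters(c(mu0 = -0.51, sigma0 = 1e-8, mu1 = 0.26,
                           sigma1 = 1e-8),
                         setNames(st$model$constraints,
                                  names(st$model$constraints)))
  set.seed(12)
  noise <- priormatch:::draw_base_noise(st$model, 1, 4000)
  nat <- priormatch:::natural_duals(lam)
  draws <- priormatch:::sample_priors_dual(st$model$prior, nat, 1, 4000,
                                           noise$prior)
  sim <- priormatch:::simulate_data_dual(st$model$likelihood, st$model$design,
                                         draws, noise$lik)
  z <- compute_target(target_quantity("y0", "prediction", rows = 1),
                      draws, sim, st$model$design)
  expect_equal(mean(z$v), 100 * plogis(-0.51), tolerance = 0.02)
})
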