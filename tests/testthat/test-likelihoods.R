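# Forward simulation of observations, link functions, and the Gumbel-Softmax
# relaxation of discrete likelihoods.

new_dual <- priormatch:::new_dual

test_that("linear predictor is the design-weighted coefficient sum", {
  X <- build_design("normal_linear")
  beta_means <- c(0.12, 0.15, -0.02, -0.03, -0.02, -0.04)
  beta <- lapply(beta_means, function(m) m) # degenerate draws, length 1
  th <- linear_predictor(X, beta)
  thm <- matrix(priormatch:::dual_value(th), 1, 6)
  expect_equal(thm[1, 1], 0.12)                 # baseline cell (new, deep)
  expect_equal(thm[1, 2], 0.12 + 0.15)          # repetition effect only
  expect_equal(thm[1, 4], 0.12 + 0.15 - 0.02 - 0.02) # rep + std + rep:std
  X0 <- design_matrix(matrix(0, 2, 2), meta = list())
  expect_equal(priormatch:::dual_value(linear_predictor(X0, list(1, 2))),
               rep(0, 2))
  expect_error(linear_predictor(X, beta[1:3]), "match")
})

test_that("inverse links are correct and round-trip with the logit", {
  expect_equal(apply_link_inverse("logit", 0), 0.5)
  expect_equal(apply_link_inverse("log", 2.91), exp(2.91))
  expect_equal(apply_link_inverse("log", 2.91), 18.357, tolerance = 1e-3)
  # round trip is exact to 1e-9 where the logistic is not saturated in
  # double precision (beyond |x| ~ 15 the 1 - p subtraction dominates)
  x <- seq(-15, 15, length.out = 101)
  p <- apply_link_inverse("logit", x)
  expect_equal(qlogis(p), x, tolerance = 1e-9)
  expect_equal(apply_link_inverse("identity", c(-5, 7)), c(-5, 7))
})

test_that("normal likelihood draws are reparameterized and exact in moments", {
  eps <- rnorm(10000)
  y <- sample_normal_likelihood(rep(0, 10000), 1, eps)
  expect_lt(abs(sd(y) - 1), 4 / sqrt(2 * 10000))
  y2 <- sample_normal_likelihood(rep(2, 5), 1e-12, rnorm(5))
  expect_equal(y2, rep(2, 5), tolerance = 1e-9)    # s -> 0 limit: y = theta
  expect_error(sample_normal_likelihood(0, -1, 0), "positive")
  # determinism: same eps, same draws
  expect_identical(sample_normal_likelihood(1:3, 2, c(.1, .2, .3)),
                   sample_normal_likelihood(1:3, 2, c(.1, .2, .3)))
})

test_that("categorical logits normalize and match the exact pmfs", {
  # Binomial(T=1, 0.5): equal logits
  l1 <- categorical_logits("binomial", 0.5, 1)
  expect_equal(l1[1, 1], l1[1, 2])
  # Binomial(T=2, 0.5): probabilities (.25, .5, .25)
  l2 <- categorical_logits("binomial", 0.5, 2)
  p2 <- exp(l2[1, ]) / sum(exp(l2[1, ]))
  expect_equal(p2, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  # general: exp-normalized logits equal dbinom / truncated dpois
  for (th in c(0.1, 0.37, 0.9)) {
    lg <- categorical_logits("binomial", th, 100)
    expect_equal(exp(lg[1, ]) / sum(exp(lg[1, ])), dbinom(0:100, 100, th),
                 tolerance = 1e-10)
  }
  for (rate in c(0.5, 18.4, 60)) {
    lg <- categorical_logits("poisson_trunc", rate, 80)
    pr <- exp(lg[1, ]) / sum(exp(lg[1, ]))
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_equal(pr, dpois(0:80, rate) / ppois(80, rate), tolerance = 1e-10)
  }
  expect_error(categorical_logits("binomial", 1.2, 10), "\\(0, 1\\)")
  expect_error(categorical_logits("poisson_trunc", -3, 10), "positive")
})

test_that("gumbel-softmax limits: single category, low temperature, identity", {
  expect_equal(gumbel_softmax_value(matrix(0, 1, 1), 5, values = 7,
                                    gumbel = matrix(0, 1, 1)), 7)
  set.seed(9)
  lg <- matrix(rnorm(10 * 5), 10, 5)
  G <- matrix(priormatch:::rgumbel(50), 10, 5)
  y_cold <- gumbel_softmax_value(lg, 0.01, gumbel = G)
  hardmax <- (0:4)[max.col(lg + G, ties.method = "first")]
  expect_equal(y_cold, hardmax, tolerance = 1e-3)
  expect_error(gumbel_softmax_value(lg, -1), "positive")
})

test_that("relaxation bias shrinks monotonically as temperature decreases", {
  # asymmetric pmf (theta = 0.2, so the smoothing bias does not cancel) and
  # common Gumbel noise across the temperatures
  set.seed(17)
  n <- 100000
  th <- 0.2; T_ <- 2
  lg <- matrix(rep(categorical_logits("binomial", th, T_), each = n), n)
  exact_mean <- T_ * th # = 0.4
  G <- matrix(priormatch:::rgumbel(n * 3), n, 3)
  bias <- vapply(c(2, 1, 0.5), function(tau)
    abs(mean(gumbel_softmax_value(lg, tau, gumbel = G)) - exact_mean), 0)
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.05)
})

test_that("gradients flow through the relaxed binomial at the study-2 truth", {
  st <- study_definition("binomial")
  lam <- st$lambda_star
  set.seed(23)
  noise <- priormatch:::draw_base_noise(st$model, 4, 25)
  nat <- priormatch:::natural_duals(lam)
  draws <- priormatch:::sample_priors_dual(st$model$prior, nat, 4, 25,
                                           noise$prior)
  sim <- priormatch:::simulate_data_dual(st$model$likelihood, st$model$design,
                                         draws, noise$lik)
  gmu0 <- priormatch:::dual_mean(sim$y)$g[1, match("mu0", lam$names)]
  expect_true(is.finite(gmu0))
  expect_gt(abs(gmu0), 0)
})

test_that("hierarchical varying effects reduce to fixed effects when zero", {
  st <- study_definition("hierarchical", participants = 4)
  lam <- st$lambda_star
  # force tau ~ 0 via tiny omega: u ~ 0
  lam2 <- hyperparameters(
    replace(to_natural(lam), c("omega0", "omega1"), c(1e-9, 1e-9)),
    setNames(lam$constraint, lam$names))
  set.seed(3)
  noise <- priormatch:::draw_base_noise(st$model, 2, 10)
  nat <- priormatch:::natural_duals(lam2)
  draws <- priormatch:::sample_priors_dual(st$model$prior, nat, 2, 10,
                                           noise$prior)
  sim <- priormatch:::simulate_data_dual(st$model$likelihood, st$model$design,
                                         draws, noise$lik)
  th <- matrix(sim$theta_nat$v, 20, 40)
  b0 <- draws$values$b0$v; b1 <- draws$values$b1$v
  day <- st$model$design$meta$day
  fixed <- outer(b0, rep(1, 40)) + outer(b1, rep(1, 40)) *
    matrix(day, 20, 40, byrow = TRUE)
  expect_equal(th, fixed, tolerance = 1e-6)
})
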