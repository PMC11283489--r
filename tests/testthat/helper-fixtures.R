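# Shared test utilities: finite-difference gradients and small run configs.

# Central finite-difference gradient of f (scalar-valued) at u.
fd_gradient <- function(f, u, h = 1e-5) {
  vapply(seq_along(u), function(i) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    (f(up) - f(um)) / (2 * h)
  }, 0)
}

# Brute-force double-loop biased squared MMD (independent of mmd2_biased).
mmd2_bruteforce <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- nrow(x); m <- nrow(y)
  kxx <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    kxx <- kxx + energy_kernel(x[i, ], x[j, ])
  kyy <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    kyy <- kyy + energy_kernel(y[i, ], y[j, ])
  kxy <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    kxy <- kxy + energy_kernel(x[i, ], y[j, ])
  kxx / n^2 + kyy / m^2 - 2 * kxy / (n * m)
}

# Small training configuration for fast end-to-end tests (overridable).
quick_config <- function(...) {
  args <- utils::modifyList(list(B = 16, E = 40, S = 30, lr0 = 0.1,
                                 window = 10), list(...))
  do.call(training_config, args)
}

# Loss of a study's model at unconstrained u under fixed common random numbers.
study_loss_fn <- function(study, expert, B, S, noise) {
  lam <- study$lambda_star
  function(u) {
    l2 <- priormatch:::set_unconstrained(lam, u)
    priormatch:::eval_loss_dual(study$model, study$plan, expert, l2,
                                B, S, noise)
  }
}
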