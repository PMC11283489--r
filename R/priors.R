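# Prior specification and differentiable (reparameterized) prior sampling.
#
# Four families cover the shipped models:
#   normal(mean, sd)            location-scale reparameterization
#   gamma(shape, rate)          implicit reparameterization via the inverse CDF
#   halfnormal(scale)           TruncatedNormal(0, scale) on (0, Inf), inverse CDF
#   lkj2(eta)                   2x2 LKJ correlation, Beta-marginal construction
#
# Hyperparameter bindings are names into the hyperparameter vector; numeric
# literals are treated as fixed constants (e.g. the LKJ shape).

#' Declare a set of parametric priors
#'
#' @param components a list; each element is `list(param =, family =, args =)`
#'   where `args` binds the family's hyperparameters either to names in the
#'   hyperparameter vector (character) or to fixed numeric constants.
#'   Families: `"normal"` (`mean`, `sd`), `"gamma"` (`shape`, `rate`),
#'   `"halfnormal"` (`scale`; a Normal(0, scale) truncated to the positive
#'   half-line), `"lkj2"` (`eta`; marginal of the off-diagonal correlation of
#'   a 2x2 LKJ matrix).
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(components) {
  fams <- c("normal", "gamma", "halfnormal", "lkj2")
  scale_args <- c("sd", "shape", "rate", "scale", "eta")
  for (cmp in components) {
    stopifnot(is.character(cmp$param), cmp$family %in% fams, is.list(cmp$args))
  }
  structure(list(components = components, scale_args = scale_args),
            class = "prior_spec")
}

#' Validate a prior spec against a hyperparameter vector
#'
#' Checks that every bound name resolves and that scale-type hyperparameters
#' (sd, shape, rate, scale) are positive-constrained.
#' @param spec a [prior_spec()].
#' @param lambda a [hyperparameters()] object.
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_prior_spec <- function(spec, lambda) {
  for (cmp in spec$components) {
    for (an in names(cmp$args)) {
      a <- cmp$args[[an]]
      if (is.character(a)) {
        i <- match(a, lambda$names)
        if (is.na(i)) stop("unresolved hyperparameter binding: ", a)
        if (an %in% spec$scale_args && lambda$constraint[i] != "positive")
          stop("scale-type hyperparameter must be positive-constrained: ", a)
      }
    }
  }
  invisible(TRUE)
}

# Resolve one binding to a scalar dual given natural-scale duals.
resolve_arg <- function(a, nat, P) {
  if (is.character(a)) nat[[a]] else new_dual(a, P = P)
}

# ---- family samplers (dual-aware, driven by supplied base noise) ------------

# Gamma(shape, rate): x = qgamma(u, shape) / rate.
# d x/d shape by implicit differentiation of the CDF:
#   F(x; a) = u  =>  dx/da = -(dF/da) / f(x; a),
# with dF/da from a central numeric difference of pgamma in the shape.
reparam_gamma <- function(shape_d, rate_d, u) {
  a <- shape_d$v
  if (a <= 0 || rate_d$v <= 0) stop("gamma shape and rate must be positive")
  x1 <- stats::qgamma(u, shape = a) # unit rate
  h <- 1e-5 * max(1, abs(a))
  dFda <- (stats::pgamma(x1, shape = a + h) -
           stats::pgamma(x1, shape = a - h)) / (2 * h)
  dens <- stats::dgamma(x1, shape = a)
  dens <- pmax(dens, 1e-300)
  dxda <- -dFda / dens
  P <- ncol(shape_d$g)
  # x = x1(shape) / rate
  v <- x1 / rate_d$v
  g <- outer(dxda / rate_d$v, shape_d$g[1, ]) +
       outer(-x1 / rate_d$v^2, rate_d$g[1, ])
  new_dual(v, g)
}

# Half-normal (TruncatedNormal(0, scale) on the positive half-line):
# x = scale * qnorm((1 + u) / 2); linear in scale, exact inverse-CDF reparam.
reparam_halfnormal <- function(scale_d, u) {
  if (scale_d$v <= 0) stop("halfnormal scale must be positive")
  z <- stats::qnorm((1 + u) / 2)
  scale_d * new_dual(z, P = ncol(scale_d$g))
}

#' Sample the off-diagonal correlation of a 2x2 LKJ matrix
#'
#' Uses the Beta-marginal construction: for a d = 2 correlation matrix under
#' LKJ(eta), the correlation satisfies (rho + 1)/2 ~ Beta(eta, eta); eta = 1
#' gives a uniform marginal on (-1, 1). The LKJ shape is a fixed constant of
#' the model, never a learned hyperparameter.
#'
#' @param eta LKJ shape, > 0.
#' @param n number of draws.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return numeric vector of correlations strictly inside (-1, 1).
#' @export
sample_lkj_correlation <- function(eta, n, seed = NULL) {
  if (eta <= 0) stop("LKJ shape must be positive")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  rho <- 2 * stats::qbeta(u, eta, eta) - 1
  pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
}

# ---- top-level sampling ------------------------------------------------------

# Base noise needed per component for (B, S) draws.
prior_noise <- function(spec, B, S) {
  n <- B * S
  noise <- list()
  for (cmp in spec$components) {
    noise[[cmp$param]] <- switch(cmp$family,
      normal     = stats::rnorm(n),
      gamma      = stats::runif(n, min = 1e-12, max = 1 - 1e-12),
      halfnormal = stats::runif(n, min = 1e-12, max = 1 - 1e-12),
      lkj2       = stats::runif(n, min = 1e-12, max = 1 - 1e-12)
    )
  }
  noise
}

# Dual prior draws for every component. `nat` is the named list of
# natural-scale scalar duals (see natural_duals), or plain numerics wrapped by
# the caller. Returns list(values = named list of duals length B*S, B =, S =).
sample_priors_dual <- function(spec, nat, B, S, noise) {
  P <- if (length(nat)) ncol(nat[[1]]$g) else 0L
  out <- list()
  for (cmp in spec$components) {
    u <- noise[[cmp$param]]
    d <- switch(cmp$family,
      normal = {
        m <- resolve_arg(cmp$args$mean, nat, P)
        s <- resolve_arg(cmp$args$sd, nat, P)
        if (s$v <= 0) stop("normal prior sd must be positive")
        dual_recycle(m, length(u)) + s * new_dual(u, P = P)
      },
      gamma = reparam_gamma(resolve_arg(cmp$args$shape, nat, P),
                            resolve_arg(cmp$args$rate, nat, P), u),
      halfnormal = reparam_halfnormal(resolve_arg(cmp$args$scale, nat, P), u),
      lkj2 = {
        eta <- cmp$args$eta
        if (is.character(eta)) stop("the LKJ shape is fixed, not learned")
        rho <- 2 * stats::qbeta(u, eta, eta) - 1
        new_dual(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12), P = P)
      }
    )
    out[[cmp$param]] <- d
  }
  list(values = out, B = B, S = S)
}

#' Draw reparameterized prior samples
#'
#' Samples theta ~ p(theta | lambda) for every component of the prior
#' specification, B x S draws per parameter. Sampling is reparameterized: the
#' draws are a deterministic function of lambda given the base noise, so fixed
#' seeds give identical draws and gradients can flow through the sampler.
#'
#' @param spec a [prior_spec()].
#' @param lambda a [hyperparameters()] object.
#' @param B,S batch size and prior-sample count.
#' @param seed integer seed.
#' @return list with `values` (named list, one numeric vector of length `B*S`
#'   per parameter, batch index fastest), `B`, `S`.
#' @export
sample_priors <- function(spec, lambda, B, S, seed) {
  stopifnot(B >= 1, S >= 1)
  validate_prior_spec(spec, lambda)
  set.seed(seed)
  noise <- prior_noise(spec, B, S)
  natv <- to_natural(lambda)
  nat <- lapply(natv, function(x) new_dual(x, P = 0L))
  draws <- sample_priors_dual(spec, nat, B, S, noise)
  draws$values <- lapply(draws$values, dual_value)
  draws
}
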