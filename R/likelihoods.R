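# Likelihood forward simulation, link functions, and the Gumbel-Softmax
# continuous relaxation for discrete outcomes.
#
# Array layout: parameter draws have length B*S (batch fastest); simulated
# responses are column-major (B*S) x N duals, i.e. element (bs, i) sits at
# index bs + B*S*(i-1).

LIN_CLIP <- 30          # linear predictors clipped before logistic/exp
PROB_CLIP <- 1e-12      # probabilities clipped before log

#' Build a design matrix object
#'
#' @param X numeric matrix with named columns (intercept column of ones where
#'   the model has one).
#' @param meta optional list of factor/selector metadata (e.g. row groupings,
#'   participant and day indices for hierarchical designs).
#' @return object of class `"design_matrix"`.
#' @export
design_matrix <- function(X, meta = list()) {
  X <- as.matrix(X)
  if (nrow(X) < 1 || anyNA(X)) stop("design matrix must be complete with N >= 1")
  structure(list(X = X, meta = meta), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$X), "x", ncol(x$X), "\n")
  print(utils::head(x$X))
  invisible(x)
}

#' Specify a likelihood
#'
#' @param family one of `"normal"`, `"binomial"`, `"poisson_trunc"`,
#'   `"hier_normal"`.
#' @param link one of `"identity"`, `"logit"`, `"log"`.
#' @param trials binomial trial count T (>= 1).
#' @param upper truncation threshold t_u for the truncated Poisson (>= 1).
#' @param temperature Gumbel-Softmax temperature tau (> 0) for discrete
#'   families.
#' @return object of class `"likelihood_spec"`.
#' @export
likelihood_spec <- function(family = c("normal", "binomial", "poisson_trunc",
                                       "hier_normal"),
                            link = c("identity", "logit", "log"),
                            trials = NULL, upper = NULL, temperature = 1) {
  family <- match.arg(family)
  link <- match.arg(link)
  ok <- switch(family,
    normal = link == "identity", hier_normal = link == "identity",
    binomial = link == "logit", poisson_trunc = link == "log")
  if (!ok) stop("link '", link, "' incompatible with family '", family, "'")
  if (family == "binomial" && (is.null(trials) || trials < 1))
    stop("binomial family needs trials >= 1")
  if (family == "poisson_trunc" && (is.null(upper) || upper < 1))
    stop("truncated Poisson needs upper >= 1")
  if (temperature <= 0) stop("relaxation temperature must be > 0")
  structure(list(family = family, link = link, trials = trials,
                 upper = upper, temperature = temperature),
            class = "likelihood_spec")
}

#' Linear predictor
#'
#' Computes `theta_lin[bs, i] = sum_k beta_k[bs] * X[i, k]`, optionally adding
#' hierarchical varying effects `u0_j + u1_j * x_i` supplied per row.
#'
#' @param design a [design_matrix()].
#' @param beta list of coefficient draw vectors (or duals), one per design
#'   column, each of length B*S.
#' @param u optional list with elements `u0`, `u1` ((B*S) x J column-major),
#'   `participant` (row -> participant index), `xvar` (row covariate values).
#' @return (B*S) x N column-major array (dual if inputs are dual).
#' @export
linear_predictor <- function(design, beta, u = NULL) {
  X <- design$X
  K <- ncol(X)
  if (length(beta) != K) stop("coefficient count does not match design columns")
  P <- max(vapply(beta, function(b) if (is_dual(b)) dual_nP(b) else 0L, 0L))
  beta <- lapply(beta, as_dual, P = P)
  n <- length(beta[[1]]$v)
  bmat <- dual_bind_list(beta)            # (n x K) column-major
  th <- dual_matmul(bmat, n, K, t(X))     # (n x N)
  if (!is.null(u)) {
    N <- nrow(X)
    jidx <- u$participant
    x <- u$xvar
    stopifnot(length(jidx) == N, length(x) == N)
    # gather participant effects per row: (n x N)
    idx0 <- as.numeric(outer(seq_len(n), (jidx - 1) * n, "+"))
    u0r <- dual_sub(as_dual(u$u0, P), idx0)
    u1r <- dual_sub(as_dual(u$u1, P), idx0)
    xfull <- new_dual(rep(x, each = n), P = P)
    th <- th + u0r + u1r * xfull
  }
  th
}

dual_bind_list <- function(xs) do.call(dual_bind, xs)

#' Inverse link
#'
#' Identity passes through; `logit` maps to the unit interval via the logistic
#' function; `log` exponentiates. Linear predictors are clipped to +/-30
#' before the logistic/exp to keep early SGD iterations finite.
#'
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param theta_lin numeric vector/array or dual.
#' @return same shape, on the natural (mean) scale.
#' @export
apply_link_inverse <- function(link, theta_lin) {
  d <- is_dual(theta_lin)
  switch(link,
    identity = theta_lin,
    logit = if (d) dual_plogis(dual_clip(theta_lin, -LIN_CLIP, LIN_CLIP))
            else stats::plogis(pmin(pmax(theta_lin, -LIN_CLIP), LIN_CLIP)),
    log = if (d) exp(dual_clip(theta_lin, -LIN_CLIP, LIN_CLIP))
          else exp(pmin(pmax(theta_lin, -LIN_CLIP), LIN_CLIP)),
    stop("unknown link: ", link)
  )
}

#' Normal likelihood draws
#'
#' `y = theta + s * eps` with standard-normal base noise `eps`; differentiable
#' in both the mean and the residual standard deviation.
#'
#' @param theta_nat mean array (numeric or dual), length n.
#' @param s residual sd draws (numeric or dual), length n or recycled per row.
#' @param eps standard normal base noise, length n (drawn by the caller so that
#'   seeds are controlled in one place).
#' @return array of draws, dual if the inputs are dual.
#' @export
sample_normal_likelihood <- function(theta_nat, s, eps) {
  sv <- dual_value(s)
  if (any(sv <= 0)) stop("residual sd must be positive")
  if (is_dual(theta_nat) || is_dual(s)) {
    P <- max(if (is_dual(theta_nat)) dual_nP(theta_nat) else 0L,
             if (is_dual(s)) dual_nP(s) else 0L)
    theta_nat <- as_dual(theta_nat, P)
    s <- as_dual(s, P)
    n <- length(theta_nat$v)
    sfull <- if (length(s$v) == n) s else dual_sub(s, rep_len(seq_along(s$v), n))
    theta_nat + sfull * new_dual(eps, P = P)
  } else {
    n <- length(theta_nat)
    theta_nat + rep_len(sv, n) * eps
  }
}

#' Categorical logits of a bounded discrete likelihood
#'
#' Log-pmf over the support (up to an additive per-element constant): binomial
#' over `{0, ..., T}` or upper-truncated Poisson over `{0, ..., t_u}` (the
#' truncation renormalization is a per-element constant and drops out of the
#' softmax).
#'
#' @param family `"binomial"` or `"poisson_trunc"`.
#' @param theta_nat success probabilities (binomial) or rates (Poisson).
#' @param size T (binomial) or t_u (truncated Poisson).
#' @return matrix `length(theta_nat)` x `(size + 1)` of logits.
#' @export
categorical_logits <- function(family, theta_nat, size) {
  v <- dual_value(theta_nat)
  cats <- 0:size
  if (family == "binomial") {
    if (any(v <= 0 | v >= 1)) stop("binomial probability must lie in (0, 1)")
    outer(log(v), cats) + outer(log1p(-v), size - cats) +
      matrix(lchoose(size, cats), length(v), size + 1, byrow = TRUE)
  } else if (family == "poisson_trunc") {
    if (any(v <= 0)) stop("Poisson rate must be positive")
    outer(log(v), cats) - v -
      matrix(lfactorial(cats), length(v), size + 1, byrow = TRUE)
  } else stop("unknown discrete family: ", family)
}

#' Gumbel-Softmax relaxed value
#'
#' Returns `sum_c softmax((logits + gumbel) / tau)[c] * value[c]`: a
#' continuous, differentiable surrogate for a categorical draw. As tau -> 0
#' with fixed noise it converges to the value at the argmax of
#' `logits + gumbel`.
#'
#' @param logits matrix n x C (or vector for a single element).
#' @param tau temperature, > 0.
#' @param values support values (length C); defaults to `0:(C-1)`.
#' @param gumbel matrix of Gumbel(0,1) noise, same shape as `logits`; drawn by
#'   the caller.
#' @param hard if `TRUE`, return the argmax category's value (straight-through
#'   style forward value); default soft.
#' @return numeric vector of length n.
#' @export
gumbel_softmax_value <- function(logits, tau, values = NULL, gumbel = NULL,
                                 hard = FALSE) {
  if (tau <= 0) stop("temperature must be positive")
  if (is.vector(logits)) logits <- matrix(logits, 1)
  C <- ncol(logits)
  if (is.null(values)) values <- 0:(C - 1)
  if (is.null(gumbel)) gumbel <- matrix(rgumbel(length(logits)), nrow(logits), C)
  A <- (logits + gumbel) / tau
  if (hard) return(values[max.col(A, ties.method = "first")])
  A <- A - A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  W <- exp(A)
  W <- W / rowSums(W)
  as.numeric(W %*% values)
}

# Gumbel(0,1) = -log(Exponential(1)).
rgumbel <- function(n) -log(stats::rexp(n))

# Dual-aware relaxed discrete sampler. theta is a dual of length n; returns a
# dual of relaxed values in [0, size]. With w = softmax((log pmf + g)/tau) and
# y = sum_c w_c c, the exact gradient is
#   dy/dtheta = (E_w[c l'_c] - E_w[c] E_w[l'_c]) / tau,
# where l'_c = d log pmf(c; theta)/d theta. Both shipped families have l'_c
# affine in c, so this collapses to Var_w(c) times a per-element factor:
#   binomial:          Var_w(c) / (theta (1 - theta) tau)
#   truncated Poisson: Var_w(c) / (theta tau).
# Per-element additive constants of the log-pmf (including the truncation
# renormalization) cancel in the softmax and are dropped; per-category
# constants are added as a single column offset.
relaxed_discrete_dual <- function(family, theta, size, tau, gumbel) {
  v <- theta$v
  cats <- 0:size
  n <- length(v)
  P <- ncol(theta$g)
  if (family == "binomial") {
    vc <- pmin(pmax(v, PROB_CLIP), 1 - PROB_CLIP)
    qv <- log(vc) - log1p(-vc)               # logit; row constants dropped
    colconst <- lchoose(size, cats)
  } else {
    vc <- pmax(v, PROB_CLIP)
    qv <- log(vc)
    colconst <- -lfactorial(cats)
  }
  A <- outer(qv, cats) + gumbel
  if (tau != 1) A <- A / tau
  A <- A + rep(colconst / tau, each = n)
  A <- exp(A - A[cbind(seq_len(n), max.col(A, ties.method = "first"))])
  mm <- A %*% cbind(cats, cats * cats)
  rs <- rowSums(A)
  wv <- mm[, 1] / rs
  if (P == 0L) return(new_dual(wv, matrix(0, n, 0)))
  varw <- mm[, 2] / rs - wv * wv
  dydt <- varw / (tau * if (family == "binomial") vc * (1 - vc) else vc)
  new_dual(wv, theta$g * dydt)
}

# ---- full forward simulation --------------------------------------------------

# Base noise for the likelihood stage.
likelihood_noise <- function(lik, N, B, S, J = NULL) {
  n <- B * S
  switch(lik$family,
    normal = list(eps = stats::rnorm(n * N)),
    hier_normal = list(eps = stats::rnorm(n * N),
                       z0 = stats::rnorm(n * J), z1 = stats::rnorm(n * J)),
    binomial = {
      g <- rgumbel(n * N * (lik$trials + 1))
      dim(g) <- c(n * N, lik$trials + 1)
      list(gumbel = g)
    },
    poisson_trunc = {
      g <- rgumbel(n * N * (lik$upper + 1))
      dim(g) <- c(n * N, lik$upper + 1)
      list(gumbel = g)
    }
  )
}

# Simulate responses given prior draws. Returns list(y =, theta_nat =, u =).
# draws$values entries are duals (or plain vectors wrapped upstream).
simulate_data_dual <- function(lik, design, draws, noise) {
  X <- design$X
  N <- nrow(X)
  B <- draws$B; S <- draws$S; n <- B * S
  vals <- draws$values
  coef_names <- design$meta$coef %||% colnames(X)
  beta <- vals[coef_names]
  if (lik$family == "hier_normal") {
    J <- design$meta$J
    tau0 <- vals[[design$meta$tau0 %||% "tau0"]]
    tau1 <- vals[[design$meta$tau1 %||% "tau1"]]
    rho <- vals[[design$meta$rho %||% "rho01"]]
    P <- dual_nP(tau0)
    z0 <- noise$z0; z1 <- noise$z1
    rhofull <- dual_sub(rho, rep_len(seq_len(n), n * J))
    t0full <- dual_sub(tau0, rep_len(seq_len(n), n * J))
    t1full <- dual_sub(tau1, rep_len(seq_len(n), n * J))
    # u = L z with L the Cholesky factor of Sigma_u
    u0 <- t0full * new_dual(z0, P = P)
    u1 <- t1full * (rhofull * new_dual(z0, P = P) +
                    sqrt(1 - rhofull * rhofull + 1e-12) * new_dual(z1, P = P))
    u <- list(u0 = u0, u1 = u1,
              participant = design$meta$participant, xvar = design$meta$day)
    th_lin <- linear_predictor(design, beta, u)
    th_nat <- apply_link_inverse(lik$link, th_lin)
    y <- sample_normal_likelihood(th_nat, vals[[design$meta$sigma %||% "s"]],
                                  noise$eps)
    return(list(y = y, theta_nat = th_nat, u = u))
  }
  th_lin <- linear_predictor(design, beta)
  th_nat <- apply_link_inverse(lik$link, th_lin)
  sfix <- design$meta$sigma_fixed
  y <- switch(lik$family,
    normal = if (!is.null(sfix)) {
      if (sfix == 0) th_nat
      else th_nat + new_dual(sfix * noise$eps, P = dual_nP(th_nat))
    } else sample_normal_likelihood(th_nat, vals[[design$meta$sigma %||% "s"]],
                                    noise$eps),
    binomial = relaxed_discrete_dual("binomial", th_nat, lik$trials,
                                     lik$temperature, noise$gumbel),
    poisson_trunc = relaxed_discrete_dual("poisson_trunc", th_nat, lik$upper,
                                          lik$temperature, noise$gumbel)
  )
  list(y = y, theta_nat = th_nat, u = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
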