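# Mini-batch SGD over the prior hyperparameters: simulate -> elicit -> loss ->
# gradient -> Adam update, for a fixed number of epochs, with a full per-epoch
# trace.

#' Bundle a generative model
#'
#' @param prior a [prior_spec()].
#' @param likelihood a [likelihood_spec()].
#' @param design a [design_matrix()].
#' @param init_fn function(void) -> [hyperparameters()], drawing the random
#'   initialization from the current RNG stream.
#' @param constraints named constraint vector for the learnable lambda (used to
#'   rebuild hyperparameter objects from traces).
#' @return object of class `"generative_model"`.
#' @export
generative_model <- function(prior, likelihood, design, init_fn = NULL,
                             constraints = NULL) {
  structure(list(prior = prior, likelihood = likelihood, design = design,
                 init_fn = init_fn, constraints = constraints),
            class = "generative_model")
}

#' Training configuration
#'
#' Algorithm parameters of the optimization: batch size B, epochs E, prior
#' samples S, and the initial learning rate of the cosine-decay-with-restarts
#' schedule used with Adam.
#'
#' @param B batch size (replicates of each statistic per epoch).
#' @param E number of epochs.
#' @param S prior samples per replicate.
#' @param lr0 initial learning rate phi^0.
#' @param period cosine-restart period in epochs.
#' @param decay multiplicative learning-rate decay applied at each restart.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed root seed for the run (fresh base noise every epoch is drawn
#'   from this stream).
#' @param window averaging window W for the final estimate.
#' @param weighting `"equal"` (default) or `"dwa"`.
#' @param dwa_temperature softmax temperature for dynamic weight averaging.
#' @param hist_max ceiling on model-side points entering histogram components.
#' @param init optional [hyperparameters()] starting value (overrides the
#'   model's initialization scheme).
#' @return list of class `"training_config"`.
#' @export
training_config <- function(B = 128, E = 600, S = 200, lr0 = 0.1, period = 50,
                            decay = 0.9, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, seed = 1, window = 30,
                            weighting = c("equal", "dwa"),
                            dwa_temperature = 2, hist_max = 1000,
                            init = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(B >= 1, E >= 1, S >= 1, lr0 > 0, window <= E)
  structure(as.list(environment()), class = "training_config")
}

#' Cosine-decay-with-restarts learning rate
#'
#' @param epoch 1-based epoch index.
#' @param lr0 initial learning rate.
#' @param period restart period (epochs).
#' @param decay factor applied to the amplitude at each restart.
#' @return learning rate for the epoch.
#' @export
cosine_restart_lr <- function(epoch, lr0, period = 50, decay = 0.9) {
  r <- (epoch - 1) %/% period
  tau <- (epoch - 1) %% period
  lr0 * decay^r * 0.5 * (1 + cos(pi * tau / period))
}

#' Plain SGD update
#'
#' One gradient step on the unconstrained scale:
#' `lambda <- lambda - delta * gradient`. Positive-constrained entries remain
#' valid on the natural scale because the step acts on their log.
#'
#' @param lambda a [hyperparameters()] object.
#' @param gradient numeric gradient of the loss wrt the unconstrained lambda.
#' @param lr step size delta.
#' @return updated [hyperparameters()] object.
#' @export
sgd_step <- function(lambda, gradient, lr) {
  if (any(!is.finite(gradient))) stop("non-finite gradient in sgd_step")
  set_unconstrained(lambda, to_unconstrained(lambda) - lr * gradient)
}

# Fresh base noise for one epoch (prior + likelihood stages).
draw_base_noise <- function(model, B, S) {
  lik <- model$likelihood
  N <- nrow(model$design$X)
  J <- model$design$meta$J
  list(prior = prior_noise(model$prior, B, S),
       lik = likelihood_noise(lik, N, B, S, J = J))
}

# Evaluate the multi-objective loss as a dual (P = length(lambda)) or plain
# (P = 0 when lambda is passed with zero-width tangents).
eval_loss_dual <- function(model, plan, expert, lambda, B, S, noise,
                           weights = NULL, hist_max = 1000L,
                           kyy_means = NULL) {
  nat <- natural_duals(lambda)
  draws <- sample_priors_dual(model$prior, nat, B, S, noise$prior)
  sim <- simulate_data_dual(model$likelihood, model$design, draws, noise$lik)
  M <- plan$M
  if (is.null(weights)) weights <- rep(1, M)
  P <- length(lambda)
  comp <- numeric(M)
  gtot <- matrix(0, 1, P)
  vtot <- 0
  for (m in seq_len(M)) {
    entry <- plan$entries[[m]]
    z <- compute_target(entry$target, draws, sim, model$design)
    st <- elicit_statistic(entry, z, B, S, hist_max = hist_max)
    ey <- expert$records[[m]]$values
    Lm <- mmd2_biased(st$values, ey, n = st$n, d = st$d,
                      kyy_mean = kyy_means[[m]])
    comp[m] <- Lm$v
    vtot <- vtot + weights[m] * Lm$v
    gtot <- gtot + weights[m] * Lm$g
  }
  list(total = vtot, grad = as.numeric(gtot), components = comp,
       weights = weights)
}

#' Train prior hyperparameters against expert statistics
#'
#' Runs exactly E epochs of mini-batch SGD: each epoch draws fresh base noise,
#' forward-simulates (B, S) draws, computes the model-implied elicited
#' statistics, evaluates the weighted MMD loss against the expert statistics,
#' and updates lambda with Adam under a cosine-decay-with-restarts schedule.
#' Non-finite gradients are recorded as divergence events and the step is
#' skipped; more than 10 consecutive such epochs abort the run.
#'
#' @param model a [generative_model()].
#' @param plan an [elicitation_plan()]; entry ids must match the expert's.
#' @param expert expert statistics (see [simulate_expert_statistics()] /
#'   [load_expert_statistics()]).
#' @param config a [training_config()].
#' @return object of class `"training_trace"`: per-epoch total and component
#'   losses, gradients, natural-scale lambda, learning rates, weights, and
#'   divergence events.
#' @export
train <- function(model, plan, expert, config) {
  stopifnot(inherits(model, "generative_model"),
            inherits(plan, "elicitation_plan"),
            inherits(config, "training_config"))
  eids <- vapply(expert$records, `[[`, "", "id")
  pids <- vapply(plan$entries, `[[`, "", "id")
  if (!identical(eids, pids))
    stop("expert statistics do not match the elicitation plan")
  set.seed(config$seed)
  lambda <- config$init
  if (is.null(lambda)) lambda <- model$init_fn()
  P <- length(lambda)
  M <- plan$M
  E <- config$E
  tr <- list(
    total = numeric(E), loss = matrix(NA_real_, E, M),
    grad = matrix(NA_real_, E, P), lambda_nat = matrix(NA_real_, E, P),
    lr = numeric(E), weights = matrix(NA_real_, E, M),
    diverged = logical(E))
  colnames(tr$loss) <- colnames(tr$weights) <- pids
  colnames(tr$grad) <- colnames(tr$lambda_nat) <- lambda$names
  madam <- numeric(P); vadam <- numeric(P); tstep <- 0
  consec_bad <- 0
  # expert-side kernel terms are constant across epochs
  kyy_means <- lapply(expert$records, function(r) {
    y <- matrix(r$values, nrow = if (r$technique == "histogram")
      length(r$values) else 1)
    -mean(pair_dist(y, y))
  })
  for (e in seq_len(E)) {
    noise <- draw_base_noise(model, config$B, config$S)
    w <- if (config$weighting == "dwa" && e > 2)
      dwa_weights(tr$loss[c(e - 2, e - 1), , drop = FALSE],
                  config$dwa_temperature)
    else rep(1, M)
    res <- eval_loss_dual(model, plan, expert, lambda, config$B, config$S,
                          noise, weights = w, hist_max = config$hist_max,
                          kyy_means = kyy_means)
    lr <- cosine_restart_lr(e, config$lr0, config$period, config$decay)
    tr$total[e] <- res$total
    tr$loss[e, ] <- res$components
    tr$grad[e, ] <- res$grad
    tr$lr[e] <- lr
    tr$weights[e, ] <- w
    if (any(!is.finite(res$grad)) || !is.finite(res$total)) {
      tr$diverged[e] <- TRUE
      consec_bad <- consec_bad + 1
      if (consec_bad > 10)
        stop("persistent non-finite losses: aborting after epoch ", e)
      tr$lambda_nat[e, ] <- to_natural(lambda)
      next
    }
    consec_bad <- 0
    tstep <- tstep + 1
    madam <- config$beta1 * madam + (1 - config$beta1) * res$grad
    vadam <- config$beta2 * vadam + (1 - config$beta2) * res$grad^2
    mhat <- madam / (1 - config$beta1^tstep)
    vhat <- vadam / (1 - config$beta2^tstep)
    lambda <- set_unconstrained(
      lambda,
      to_unconstrained(lambda) - lr * mhat / (sqrt(vhat) + config$adam_eps))
    tr$lambda_nat[e, ] <- to_natural(lambda)
  }
  structure(list(epochs = E, total = tr$total, loss = tr$loss, grad = tr$grad,
                 lambda_nat = tr$lambda_nat, lr = tr$lr, weights = tr$weights,
                 diverged = tr$diverged, names = lambda$names,
                 constraint = lambda$constraint, config = config,
                 final_lambda = lambda),
            class = "training_trace")
}

#' @export
print.training_trace <- function(x, ...) {
  cat("<training_trace>", x$epochs, "epochs,", length(x$names),
      "hyperparameters\n")
  cat("final total loss:", format(utils::tail(x$total, 1)), "\n")
  invisible(x)
}

#' Final estimate from a training trace
#'
#' Entry-wise arithmetic mean of the natural-scale hyperparameters over the
#' last `window` epochs.
#'
#' @param trace a `"training_trace"`.
#' @param window number of trailing epochs to average (W <= E), default 30.
#' @return a [hyperparameters()] object.
#' @export
final_estimate <- function(trace, window = 30) {
  E <- trace$epochs
  stopifnot(window >= 1, window <= E)
  rows <- seq(E - window + 1, E)
  v <- colMeans(trace$lambda_nat[rows, , drop = FALSE])
  hyperparameters(stats::setNames(v, trace$names),
                  stats::setNames(trace$constraint, trace$names))
}

#' Convergence diagnostics for a training trace
#'
#' Reports per-component loss slopes over the last quarter of training, the
#' maximum absolute gradient over the last `window` epochs, and the maximum
#' natural-scale change of any hyperparameter over the same window. The run is
#' flagged non-converged when the total-loss slope is positive or the maximum
#' absolute gradient exceeds `grad_tol`.
#'
#' @param trace a `"training_trace"`.
#' @param window trailing window for gradient/stability summaries.
#' @param grad_tol gradient threshold for the convergence flag.
#' @return list with `loss_slopes`, `total_slope`, `max_abs_grad`,
#'   `lambda_stability`, `divergence_events`, `converged`.
#' @export
convergence_report <- function(trace, window = 30, grad_tol = Inf) {
  E <- trace$epochs
  window <- min(window, E)
  q4 <- seq(max(1, floor(3 * E / 4)), E)
  slope <- function(yv) {
    if (length(q4) < 2 || all(!is.finite(yv))) return(NA_real_)
    unname(stats::coef(stats::lm(yv ~ q4))[2])
  }
  loss_slopes <- apply(trace$loss[q4, , drop = FALSE], 2, slope)
  total_slope <- slope(trace$total[q4])
  wrows <- seq(E - window + 1, E)
  max_abs_grad <- max(abs(trace$grad[wrows, ]), na.rm = TRUE)
  lam <- trace$lambda_nat[wrows, , drop = FALSE]
  stability <- max(apply(lam, 2, function(z) diff(range(z))))
  list(loss_slopes = loss_slopes, total_slope = total_slope,
       max_abs_grad = max_abs_grad, lambda_stability = stability,
       divergence_events = sum(trace$diverged),
       converged = is.finite(total_slope) && total_slope <= 0 &&
         max_abs_grad <= grad_tol)
}

#' Random initialization of the hyperparameters for a study
#'
#' Location entries are drawn from a normal around a study-scale anchor and
#' positive entries are initialized on the log scale (the scheme of the
#' shipped studies; see the package vignette).
#'
#' @param study study id (see [study_definition()]) or a `"generative_model"`.
#' @param seed integer seed.
#' @return a [hyperparameters()] object.
#' @export
initialize_hyperparameters <- function(study, seed) {
  model <- if (inherits(study, "generative_model")) study
           else study_definition(study)$model
  set.seed(seed)
  model$init_fn()
}
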