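# Desk-scale toy model with a closed-form prior predictive, used as a fast
# end-to-end oracle for the elicitation loop:
#   theta ~ Normal(mu, sigma),  y = theta + s_fixed * eps
# so marginally y ~ Normal(mu, sqrt(sigma^2 + s_fixed^2)).

#' Define the one-parameter toy model
#'
#' @param s_fixed known residual standard deviation (>= 0; 0 means `y = theta`).
#' @param technique `"quantiles"` or `"moments"`.
#' @return list with `model` (a [generative_model()]) and `plan`.
#' @export
toy_model <- function(s_fixed = 0.5,
                      technique = c("quantiles", "moments")) {
  technique <- match.arg(technique)
  cons <- c(mu = "unconstrained", sigma = "positive")
  design <- design_matrix(cbind(`(Intercept)` = 1),
                          meta = list(coef = "theta", sigma_fixed = s_fixed))
  model <- generative_model(
    prior = prior_spec(list(list(param = "theta", family = "normal",
                                 args = list(mean = "mu", sd = "sigma")))),
    likelihood = likelihood_spec("normal", "identity"),
    design = design,
    init_fn = function() hyperparameters(
      c(mu = stats::rnorm(1, 0, 0.1), sigma = exp(stats::runif(1, -2, 0))),
      cons),
    constraints = cons)
  tech <- if (technique == "quantiles") elicitation_technique("quantiles")
          else elicitation_technique("moments")
  plan <- elicitation_plan(
    plan_entry(target_quantity("y", "prediction", rows = 1L), tech))
  list(model = model, plan = plan)
}

#' Simulated expert for the toy model
#'
#' Statistics of the closed-form prior predictive
#' `Normal(mu, sqrt(sigma^2 + s_fixed^2))`, obtained by forward simulation.
#'
#' @param mu,sigma ground-truth hyperparameters (sigma > 0).
#' @param s_fixed known residual sd.
#' @param technique `"quantiles"` or `"moments"`.
#' @param S number of prior-predictive draws.
#' @param seed oracle seed.
#' @return `"expert_statistics"` object with one record.
#' @export
make_toy_expert <- function(mu, sigma, s_fixed = 0.5,
                            technique = c("quantiles", "moments"),
                            S = 10000, seed = 99) {
  technique <- match.arg(technique)
  if (sigma <= 0) stop("sigma must be positive")
  toy <- toy_model(s_fixed, technique)
  study <- structure(list(id = "toy", model = toy$model, plan = toy$plan,
                          lambda_star = hyperparameters(
                            c(mu = mu, sigma = sigma),
                            c(mu = "unconstrained", sigma = "positive")),
                          defaults = toy_defaults(), oracle_seed = seed),
                     class = "study_definition")
  simulate_expert_statistics(study, S_expert = S, seed = seed)
}

toy_defaults <- function() training_config(B = 32, E = 200, S = 50, lr0 = 0.1,
                                           window = 30)

#' Recover the toy model's hyperparameters
#'
#' Closed-loop miniature of the recovery studies: trains on the output of
#' [make_toy_expert()] and returns the final estimate.
#'
#' @param mu,sigma ground truth.
#' @param s_fixed known residual sd.
#' @param technique elicitation technique.
#' @param config a [training_config()]; default is a fast desk-scale setting.
#' @param seed training seed.
#' @return list with `estimate` (named natural-scale vector), `trace`.
#' @export
recover_toy <- function(mu = 2, sigma = 0.5, s_fixed = 0.5,
                        technique = "quantiles", config = NULL, seed = 1) {
  toy <- toy_model(s_fixed, technique)
  expert <- make_toy_expert(mu, sigma, s_fixed, technique)
  config <- config %||% toy_defaults()
  config$seed <- seed
  trace <- train(toy$model, toy$plan, expert, config)
  est <- final_estimate(trace, window = min(config$window, config$E))
  list(estimate = to_natural(est), trace = trace)
}
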