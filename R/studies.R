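# The four closed-loop recovery studies: generative models, designs,
# ground-truth hyperparameters, elicitation plans, initialization schemes, and
# the simulated-expert oracle.

STUDY_IDS <- c("normal_linear", "binomial", "poisson", "hierarchical")

#' Build the design matrix of a study
#'
#' * `normal_linear`: the 6 cells of a 2 (repetition: new/repeated) x 3
#'   (encoding depth: deep/standard/shallow) between-subject factorial with
#'   treatment contrasts; baselines are *new* and *deep*.
#' * `binomial`: 31 axillary-node counts spanning 0-59, containing the seven
#'   elicitation design points \{0, 5, 10, 15, 20, 25, 30\} exactly.
#' * `poisson`: 50 synthetic US states; urban share evenly spaced on
#'   38.7-94.7 percent (standardized in the design; see the vignette) and a
#'   3-level voting factor (Democrat baseline) assigned cyclically.
#' * `hierarchical`: `participants` x days 0-9 long format (one row per
#'   participant-day).
#'
#' @param id study id.
#' @param participants number of participants for the hierarchical study.
#' @return a [design_matrix()].
#' @export
build_design <- function(id, participants = 200) {
  switch(id,
    normal_linear = {
      # rows: (new,deep) (rep,deep) (new,std) (rep,std) (new,shw) (rep,shw)
      X <- rbind(c(1, 0, 0, 0, 0, 0),
                 c(1, 1, 0, 0, 0, 0),
                 c(1, 0, 1, 0, 0, 0),
                 c(1, 1, 1, 0, 1, 0),
                 c(1, 0, 0, 1, 0, 0),
                 c(1, 1, 0, 1, 0, 1))
      colnames(X) <- c("(Intercept)", "rep", "std", "shw", "rep:std", "rep:shw")
      design_matrix(X, meta = list(
        coef = paste0("b", 0:5), sigma = "s",
        enc = list(deep = c(1, 2), std = c(3, 4), shw = c(5, 6)),
        rep = list(new = c(1, 3, 5), repeated = c(2, 4, 6))))
    },
    binomial = {
      x <- c(0:25, 30, 35, 40, 45, 59)
      X <- cbind(`(Intercept)` = 1, nodes = x)
      design_matrix(X, meta = list(
        coef = c("b0", "b1"),
        design_points = match(c(0, 5, 10, 15, 20, 25, 30), x)))
    },
    poisson = {
      urban <- seq(38.7, 94.7, length.out = 50)
      z <- (urban - mean(urban)) / stats::sd(urban)
      lev <- rep_len(c("Democrat", "Republican", "Swing"), 50)
      X <- cbind(`(Intercept)` = 1, urban = z,
                 repub = as.numeric(lev == "Republican"),
                 swing = as.numeric(lev == "Swing"))
      design_matrix(X, meta = list(
        coef = paste0("b", 0:3),
        groups = split(seq_len(50), lev),
        states = c(0, 13, 14, 35, 37, 48) + 1L))
    },
    hierarchical = {
      J <- participants
      day <- rep(0:9, each = J)
      X <- cbind(`(Intercept)` = 1, day = day)
      design_matrix(X, meta = list(
        coef = c("b0", "b1"), sigma = "s",
        tau0 = "tau0", tau1 = "tau1", rho = "rho01",
        J = J, participant = rep(seq_len(J), times = 10), day = day,
        day_rows = lapply(0:9, function(d) which(day == d))))
    },
    stop("unknown study id: ", id, " (valid: ",
         paste(STUDY_IDS, collapse = ", "), ")")
  )
}

quartiles <- function() elicitation_technique("quantiles", c(0.25, 0.5, 0.75))

study_plan <- function(id, design) {
  meta <- design$meta
  switch(id,
    normal_linear = {
      ents <- c(
        lapply(names(meta$enc), function(l) plan_entry(
          target_quantity(paste0("enc_", l), "group_mean", rows = meta$enc[[l]]),
          quartiles())),
        lapply(names(meta$rep), function(l) plan_entry(
          target_quantity(paste0("rep_", l), "group_mean", rows = meta$rep[[l]]),
          quartiles())),
        lapply(names(meta$enc), function(l) plan_entry(
          target_quantity(paste0("dptj_", l), "group_difference",
                          rows_a = intersect(meta$enc[[l]], meta$rep$repeated),
                          rows_b = intersect(meta$enc[[l]], meta$rep$new)),
          quartiles())),
        list(plan_entry(target_quantity("r2", "r_squared"),
                        elicitation_technique("histogram"))))
      do.call(elicitation_plan, ents)
    },
    binomial = {
      xs <- c(0, 5, 10, 15, 20, 25, 30)
      ents <- lapply(seq_along(meta$design_points), function(k) plan_entry(
        target_quantity(paste0("deaths_x", xs[k]), "prediction",
                        rows = meta$design_points[k]),
        quartiles()))
      do.call(elicitation_plan, ents)
    },
    poisson = {
      ents <- c(
        lapply(names(meta$groups), function(l) plan_entry(
          target_quantity(paste0("laws_", tolower(l)), "group_mean",
                          rows = meta$groups[[l]]),
          quartiles())),
        lapply(meta$states, function(r) plan_entry(
          target_quantity(paste0("laws_state", r - 1L), "prediction", rows = r),
          elicitation_technique("histogram"))))
      do.call(elicitation_plan, ents)
    },
    hierarchical = {
      days <- c(0, 2, 5, 6, 9)
      ents <- c(
        lapply(days, function(d) plan_entry(
          target_quantity(paste0("rt_day", d), "group_mean",
                          rows = meta$day_rows[[d + 1L]]),
          quartiles())),
        list(plan_entry(target_quantity("s", "parameter", parameter = "s"),
                        elicitation_technique("moments"))),
        lapply(c(0, 9), function(d) plan_entry(
          target_quantity(paste0("r2_day", d), "r_squared",
                          rows = meta$day_rows[[d + 1L]]),
          elicitation_technique("histogram"))))
      do.call(elicitation_plan, ents)
    }
  )
}

study_prior <- function(id) {
  norm_coef <- function(k) lapply(k, function(i) list(
    param = paste0("b", i), family = "normal",
    args = list(mean = paste0("mu", i), sd = paste0("sigma", i))))
  switch(id,
    normal_linear = prior_spec(c(norm_coef(0:5), list(
      list(param = "s", family = "gamma",
           args = list(shape = "alpha", rate = "beta"))))),
    binomial = prior_spec(norm_coef(0:1)),
    poisson = prior_spec(norm_coef(0:3)),
    hierarchical = prior_spec(c(norm_coef(0:1), list(
      list(param = "tau0", family = "halfnormal", args = list(scale = "omega0")),
      list(param = "tau1", family = "halfnormal", args = list(scale = "omega1")),
      list(param = "rho01", family = "lkj2", args = list(eta = 1)),
      list(param = "s", family = "gamma",
           args = list(shape = "alpha", rate = "beta")))))
  )
}

study_lambda_star <- function(id) {
  switch(id,
    normal_linear = hyperparameters(
      c(mu0 = 0.12, sigma0 = 0.02, mu1 = 0.15, sigma1 = 0.02,
        mu2 = -0.02, sigma2 = 0.06, mu3 = -0.03, sigma3 = 0.06,
        mu4 = -0.02, sigma4 = 0.03, mu5 = -0.04, sigma5 = 0.03,
        alpha = 20, beta = 200),
      constraints_for("normal_linear")),
    binomial = hyperparameters(
      c(mu0 = -0.51, sigma0 = 0.06, mu1 = 0.26, sigma1 = 0.04),
      constraints_for("binomial")),
    poisson = hyperparameters(
      c(mu0 = 2.91, sigma0 = 0.07, mu1 = 0.23, sigma1 = 0.05,
        mu2 = -1.51, sigma2 = 0.135, mu3 = -0.61, sigma3 = 0.105),
      constraints_for("poisson")),
    hierarchical = hyperparameters(
      c(mu0 = 250.40, sigma0 = 7.27, mu1 = 30.26, sigma1 = 4.82,
        omega0 = 33, omega1 = 23, alpha = 200, beta = 8),
      constraints_for("hierarchical"))
  )
}

constraints_for <- function(id) {
  nm <- switch(id,
    normal_linear = c(paste0(rep(c("mu", "sigma"), 6),
                             rep(0:5, each = 2)), "alpha", "beta"),
    binomial = paste0(rep(c("mu", "sigma"), 2), rep(0:1, each = 2)),
    poisson = paste0(rep(c("mu", "sigma"), 4), rep(0:3, each = 2)),
    hierarchical = c("mu0", "sigma0", "mu1", "sigma1", "omega0", "omega1",
                     "alpha", "beta"))
  stats::setNames(ifelse(grepl("^mu", nm), "unconstrained", "positive"), nm)
}

# Random initialization schemes. Studies 1-3 follow the pattern of the
# normal-linear study (locations near zero, log prior scales uniform on
# [-4, -2], log Gamma parameters near a weak guess); the hierarchical study
# anchors locations and scales at the magnitude of the response (hundreds of
# ms). Drawn from the current RNG stream.
study_init_fn <- function(id) {
  cons <- constraints_for(id)
  force(cons)
  switch(id,
    normal_linear = function() {
      v <- c(stats::rnorm(6, 0, 0.1), exp(stats::runif(6, -4, -2)),
             exp(stats::rnorm(1, 3, 0.1)), exp(stats::rnorm(1, 5, 0.1)))
      nm <- names(cons)
      ord <- c(paste0("mu", 0:5), paste0("sigma", 0:5), "alpha", "beta")
      hyperparameters(stats::setNames(v, ord)[nm], cons)
    },
    binomial = function() {
      v <- stats::setNames(numeric(4), names(cons))
      v[c("mu0", "mu1")] <- stats::rnorm(2, 0, 0.1)
      v[c("sigma0", "sigma1")] <- exp(stats::runif(2, -4, -2))
      hyperparameters(v, cons)
    },
    poisson = function() {
      v <- stats::setNames(numeric(8), names(cons))
      v[paste0("mu", 0:3)] <- stats::rnorm(4, 0, 0.1)
      v[paste0("sigma", 0:3)] <- exp(stats::runif(4, -4, -2))
      hyperparameters(v, cons)
    },
    hierarchical = function() {
      v <- c(mu0 = stats::rnorm(1, 200, 20), sigma0 = exp(stats::rnorm(1, log(5), 0.2)),
             mu1 = stats::rnorm(1, 10, 5), sigma1 = exp(stats::rnorm(1, log(5), 0.2)),
             omega0 = exp(stats::rnorm(1, log(20), 0.2)),
             omega1 = exp(stats::rnorm(1, log(20), 0.2)),
             alpha = exp(stats::rnorm(1, 5, 0.1)),
             beta = exp(stats::rnorm(1, 2, 0.1)))
      hyperparameters(v, cons)
    }
  )
}

study_likelihood <- function(id, temperature = 1) {
  switch(id,
    normal_linear = likelihood_spec("normal", "identity"),
    binomial = likelihood_spec("binomial", "logit", trials = 100,
                               temperature = temperature),
    poisson = likelihood_spec("poisson_trunc", "log", upper = 80,
                              temperature = temperature),
    hierarchical = likelihood_spec("hier_normal", "identity")
  )
}

# Expert-anchored initialization for the hierarchical study: the analyst reads
# the baseline off the elicited day-0 median and the slope off the day-9/day-0
# medians, then initializes locations there (scales follow the usual log-scale
# scheme at the response's order of magnitude). Uses the current RNG stream.
init_anchor_hierarchical <- function(expert) {
  val <- function(id) {
    for (r in expert$records) if (identical(r$id, id)) return(r$values)
    NULL
  }
  q0 <- val("rt_day0.quantiles")
  q9 <- val("rt_day9.quantiles")
  m0 <- if (is.null(q0)) 200 else q0[2]
  sl <- if (is.null(q9)) 10 else (q9[2] - m0) / 9
  hyperparameters(
    c(mu0 = stats::rnorm(1, m0, 5),
      sigma0 = exp(stats::rnorm(1, log(5), 0.2)),
      mu1 = stats::rnorm(1, sl, 2),
      sigma1 = exp(stats::rnorm(1, log(5), 0.2)),
      omega0 = exp(stats::rnorm(1, log(20), 0.2)),
      omega1 = exp(stats::rnorm(1, log(20), 0.2)),
      alpha = exp(stats::rnorm(1, 5, 0.1)),
      beta = exp(stats::rnorm(1, 2, 0.1))),
    constraints_for("hierarchical"))
}

# Per-study default algorithm parameters (the training configuration).
study_defaults <- function(id) {
  switch(id,
    normal_linear = training_config(B = 128, E = 600, S = 200, lr0 = 0.1),
    binomial = training_config(B = 128, E = 600, S = 200, lr0 = 0.1),
    poisson = training_config(B = 128, E = 600, S = 200, lr0 = 0.1),
    hierarchical = training_config(B = 128, E = 400, S = 200, lr0 = 0.25)
  )
}

#' Retrieve a study definition
#'
#' Bundles everything a closed-loop recovery run needs: the generative model,
#' the ground-truth hyperparameters lambda*, the elicitation plan, the default
#' training configuration, and the default oracle seed.
#'
#' @param id one of `"normal_linear"`, `"binomial"`, `"poisson"`,
#'   `"hierarchical"`.
#' @param participants participant count for the hierarchical study (the
#'   reference setting is 200; smaller values give faster, desk-scale runs).
#' @param temperature Gumbel-Softmax temperature for the discrete studies.
#' @return list of class `"study_definition"` with elements `id`, `model`,
#'   `lambda_star`, `plan`, `defaults`, `oracle_seed`.
#' @export
study_definition <- function(id, participants = 200, temperature = 1) {
  id <- match.arg(id, STUDY_IDS)
  design <- build_design(id, participants = participants)
  model <- generative_model(
    prior = study_prior(id),
    likelihood = study_likelihood(id, temperature = temperature),
    design = design,
    init_fn = study_init_fn(id),
    constraints = constraints_for(id))
  structure(list(id = id, model = model,
                 lambda_star = study_lambda_star(id),
                 plan = study_plan(id, design),
                 defaults = study_defaults(id),
                 init_anchor = if (id == "hierarchical")
                   init_anchor_hierarchical,
                 oracle_seed = 5000L + match(id, STUDY_IDS)),
            class = "study_definition")
}

#' Simulate expert-elicited statistics from a ground truth
#'
#' Plays the "simulated expert": forward-simulates the study's generative model
#' at `lambda_star` with a single large prior sample, applies each planned
#' elicitation technique, and returns one expert-side replicate per statistic.
#' Deterministic given the seed.
#'
#' @param study a [study_definition()] (or a study id string).
#' @param lambda_star ground-truth [hyperparameters()]; defaults to the
#'   study's reference values.
#' @param S_expert number of prior-predictive draws behind the expert's
#'   statistics.
#' @param seed oracle seed (kept separate from training seeds).
#' @param hist_size number of draws retained for histogram statistics.
#' @return object of class `"expert_statistics"`: list with `records` (one per
#'   plan entry: id, target, technique, values) and provenance attributes.
#' @export
simulate_expert_statistics <- function(study, lambda_star = NULL,
                                       S_expert = 10000, seed = NULL,
                                       hist_size = 1000) {
  if (is.character(study)) study <- study_definition(study)
  lambda_star <- lambda_star %||% study$lambda_star
  if (!setequal(lambda_star$names, study$model$constraints |> names()))
    stop("incomplete ground-truth hyperparameter vector")
  seed <- seed %||% study$oracle_seed
  model <- study$model
  set.seed(seed)
  B <- 1L; S <- as.integer(S_expert)
  noise <- draw_base_noise(model, B, S)
  nat <- lapply(to_natural(lambda_star), function(x) new_dual(x, P = 0L))
  draws <- sample_priors_dual(model$prior, nat, B, S, noise$prior)
  sim <- simulate_data_dual(model$likelihood, model$design, draws, noise$lik)
  records <- lapply(study$plan$entries, function(entry) {
    z <- compute_target(entry$target, draws, sim, model$design)
    st <- elicit_statistic(entry, z, B, S, hist_max = hist_size)
    list(id = entry$id, target = entry$target$id,
         technique = entry$technique$kind,
         p = if (entry$technique$kind == "quantiles") entry$technique$p,
         values = as.numeric(dual_value(st$values)))
  })
  structure(list(records = records),
            class = "expert_statistics",
            lambda_star = to_natural(lambda_star),
            S_expert = S, seed = seed, study = study$id)
}

#' @export
print.expert_statistics <- function(x, ...) {
  cat("<expert_statistics>", length(x$records), "statistics")
  st <- attr(x, "study")
  if (!is.null(st)) cat(" (study:", st, ")")
  cat("\n")
  for (r in x$records)
    cat(sprintf("  %-28s %-10s n=%d\n", r$id, r$technique, length(r$values)))
  invisible(x)
}

#' Run a closed-loop recovery study
#'
#' Generates expert statistics at the ground truth, trains the hyperparameters
#' on them, and reports the final estimate together with per-hyperparameter
#' natural-scale recovery errors.
#'
#' @param study a [study_definition()] or study id.
#' @param config a [training_config()]; defaults to the study's.
#' @param seed training seed.
#' @param oracle_seed seed of the simulated expert.
#' @param S_expert prior draws behind the expert statistics.
#' @param expert optionally, precomputed expert statistics (skips the oracle).
#' @return list of class `"study_result"` with `study`, `lambda_star`,
#'   `expert`, `trace`, `estimate`, `errors` (estimate minus truth, natural
#'   scale).
#' @export
run_study <- function(study, config = NULL, seed = 1, oracle_seed = NULL,
                      S_expert = 10000, expert = NULL) {
  if (is.character(study)) study <- study_definition(study)
  config <- config %||% study$defaults
  config$seed <- seed
  if (is.null(expert))
    expert <- simulate_expert_statistics(study, S_expert = S_expert,
                                         seed = oracle_seed)
  if (is.null(config$init) && !is.null(study$init_anchor)) {
    set.seed(seed)
    config$init <- study$init_anchor(expert)
  }
  trace <- train(study$model, study$plan, expert, config)
  est <- final_estimate(trace, window = min(config$window, config$E))
  truth <- to_natural(study$lambda_star)
  errors <- to_natural(est)[names(truth)] - truth
  structure(list(study = study$id, lambda_star = truth, expert = expert,
                 trace = trace, estimate = est, errors = errors),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$study, "\n")
  print(data.frame(name = names(x$lambda_star), truth = x$lambda_star,
                   estimate = to_natural(x$estimate)[names(x$lambda_star)],
                   error = x$errors, row.names = NULL))
  invisible(x)
}
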