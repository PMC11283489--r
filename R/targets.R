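# Target quantities z_i = g_i(theta) and elicitation techniques f_j reducing
# them to elicited statistics t_m = f_j(z_i).
#
# Statistics are computed across the S (prior-sample) axis, giving B per-batch
# replicates of each statistic; the expert side holds a single large-S
# replicate.

#' Define a target quantity
#'
#' @param id unique identifier within a plan.
#' @param kind one of `"parameter"`, `"prediction"`, `"group_mean"`,
#'   `"group_difference"`, `"marginal_mean"`, `"r_squared"`.
#' @param ... selector fields: `parameter` (name) for `"parameter"`; `rows`
#'   for `"prediction"`/`"group_mean"`/`"r_squared"` (for `"r_squared"` the
#'   variance is taken across these design rows); `rows_a`, `rows_b` for
#'   `"group_difference"` (mean over `rows_a` minus mean over `rows_b`);
#'   `groups` (list of row-index vectors, one per cell) for `"marginal_mean"`.
#' @return object of class `"target_quantity"`.
#' @export
target_quantity <- function(id, kind = c("parameter", "prediction",
                                         "group_mean", "group_difference",
                                         "marginal_mean", "r_squared"), ...) {
  kind <- match.arg(kind)
  structure(c(list(id = id, kind = kind), list(...)),
            class = "target_quantity")
}

#' Define an elicitation technique
#'
#' @param kind `"quantiles"`, `"moments"` or `"histogram"`.
#' @param p quantile probabilities (strictly increasing, in (0,1)); default
#'   quartiles `c(0.25, 0.5, 0.75)`.
#' @return object of class `"elicitation_technique"`.
#' @export
elicitation_technique <- function(kind = c("quantiles", "moments", "histogram"),
                                  p = c(0.25, 0.5, 0.75)) {
  kind <- match.arg(kind)
  if (kind == "quantiles") {
    if (any(p <= 0) || any(p >= 1) || is.unsorted(p, strictly = TRUE))
      stop("quantile probabilities must be strictly increasing inside (0, 1)")
  }
  structure(list(kind = kind, p = p), class = "elicitation_technique")
}

#' Assemble an elicitation plan
#'
#' An ordered list of (target quantity, technique) pairs; each pair yields one
#' elicited statistic and one loss component.
#'
#' @param ... entries created with [plan_entry()].
#' @return object of class `"elicitation_plan"`.
#' @export
elicitation_plan <- function(...) {
  entries <- list(...)
  if (length(entries) < 1) stop("an elicitation plan needs at least one entry")
  ids <- vapply(entries, function(e) e$target$id, "")
  structure(list(entries = entries, M = length(entries), ids = ids),
            class = "elicitation_plan")
}

#' One plan entry
#' @param target a [target_quantity()].
#' @param technique an [elicitation_technique()].
#' @export
plan_entry <- function(target, technique) {
  stopifnot(inherits(target, "target_quantity"),
            inherits(technique, "elicitation_technique"))
  list(target = target, technique = technique,
       id = paste(target$id, technique$kind, sep = "."))
}

# ---- target computation -------------------------------------------------------

# Mean of y over a set of design rows; y is a (n x N) column-major dual.
row_group_mean <- function(y, n, rows) {
  idx <- as.numeric(outer(seq_len(n), (rows - 1) * n, "+"))
  dual_rowmeans(dual_sub(y, idx), n, length(rows))
}

#' Compute a target quantity
#'
#' Maps simulated draws/observations to the target's scale: a named parameter's
#' draws, predictions at design rows, (differences of) group means of the
#' predictive observations, or the predictive R-squared across design rows.
#'
#' @param tq a [target_quantity()].
#' @param draws prior draws (list as returned by [sample_priors()] /
#'   `sample_priors_dual`).
#' @param sim simulated data (list with `y`, `theta_nat`).
#' @param design a [design_matrix()].
#' @return array of length B*S (dual when the inputs are dual); for
#'   `"prediction"` with several rows, one column per row.
#' @export
compute_target <- function(tq, draws, sim, design) {
  n <- draws$B * draws$S
  switch(tq$kind,
    parameter = {
      v <- draws$values[[tq$parameter]]
      if (is.null(v)) stop("unknown parameter: ", tq$parameter)
      v
    },
    prediction = {
      idx <- as.numeric(outer(seq_len(n), (tq$rows - 1) * n, "+"))
      dual_sub(sim$y, idx)
    },
    group_mean = {
      if (length(tq$rows) < 1) stop("empty group selection")
      row_group_mean(sim$y, n, tq$rows)
    },
    group_difference = {
      if (length(tq$rows_a) < 1 || length(tq$rows_b) < 1)
        stop("empty group selection")
      row_group_mean(sim$y, n, tq$rows_a) - row_group_mean(sim$y, n, tq$rows_b)
    },
    marginal_mean = {
      gm <- lapply(tq$groups, function(rows) row_group_mean(sim$y, n, rows))
      acc <- gm[[1]]
      if (length(gm) > 1) for (k in 2:length(gm)) acc <- acc + gm[[k]]
      acc * (1 / length(gm))
    },
    r_squared = {
      rows <- tq$rows %||% seq_len(nrow(design$X))
      idx <- as.numeric(outer(seq_len(n), (rows - 1) * n, "+"))
      r_squared(dual_sub(sim$theta_nat, idx), dual_sub(sim$y, idx),
                n = n, N = length(rows))
    }
  )
}

#' Predictive R-squared
#'
#' Per simulation, the variance of the modeled predictive means across design
#' rows divided by the variance of the predictive observations:
#' `R^2 = var(theta_i) / var(y_i)` (sample variance, same divisor in numerator
#' and denominator). Degenerate draws with (near-)zero response variance give
#' 0 (with a warning attribute rather than NaN).
#'
#' @param theta,y (n x N) column-major arrays (numeric or dual).
#' @param n number of simulations (B*S); inferred for plain matrices.
#' @param N number of design rows.
#' @return length-n array of R-squared values (dual when inputs are dual).
#' @export
r_squared <- function(theta, y, n = NULL, N = NULL) {
  plain <- !is_dual(theta) && !is_dual(y)
  if (plain && is.matrix(theta)) { n <- nrow(theta); N <- ncol(theta) }
  if (N < 2) stop("r_squared needs at least two design rows")
  P <- max(if (is_dual(theta)) dual_nP(theta) else 0L,
           if (is_dual(y)) dual_nP(y) else 0L)
  theta <- as_dual(theta, P); y <- as_dual(y, P)
  vt <- dual_rowvar(theta, n, N, divisor = "n-1")
  vy <- dual_rowvar(y, n, N, divisor = "n-1")
  bad <- vy$v <= 1e-300
  out <- vt / new_dual(pmax(vy$v, 1e-300), vy$g)
  if (any(bad)) {
    out$v[bad] <- 0
    out$g[bad, ] <- 0
    attr(out, "zero_variance") <- sum(bad)
  }
  if (plain) dual_value(out) else out
}

# ---- elicitation techniques ---------------------------------------------------

#' Quantile-based elicitation
#'
#' Per batch element, empirical quantiles (linear interpolation between order
#' statistics, the type-7 rule) across the S prior-sample axis.
#'
#' @param z length B*S array (numeric or dual), batch index fastest.
#' @param B,S batch size and sample count (S >= 2).
#' @param p quantile probabilities in (0,1).
#' @return B x |p| array, column-major (dual when `z` is dual).
#' @export
quantile_elicit <- function(z, B, S, p = c(0.25, 0.5, 0.75)) {
  if (any(p <= 0) || any(p >= 1)) stop("quantile probabilities must be in (0,1)")
  if (S < 2) stop("quantile elicitation needs S >= 2")
  d <- as_dual(z, if (is_dual(z)) dual_nP(z) else 0L)
  vm <- matrix(d$v, B, S)
  P <- ncol(d$g)
  np <- length(p)
  h <- (S - 1) * p + 1
  j <- pmin(floor(h), S - 1)
  gam <- h - j
  vout <- matrix(0, B, np)
  gout <- matrix(0, B * np, P)
  for (b in seq_len(B)) {
    o <- order(vm[b, ])
    lo <- b + B * (o[j] - 1)       # flat indices into z
    hi <- b + B * (o[j + 1] - 1)
    vout[b, ] <- (1 - gam) * d$v[lo] + gam * d$v[hi]
    if (P > 0) {
      rows <- b + B * (seq_len(np) - 1)
      gout[rows, ] <- (1 - gam) * d$g[lo, , drop = FALSE] +
        gam * d$g[hi, , drop = FALSE]
    }
  }
  out <- new_dual(as.numeric(vout), gout)
  if (is_dual(z)) out else dual_value(out)
}

#' Moment-based elicitation
#'
#' Per batch element, the mean and standard deviation across the S axis (the
#' standard deviation uses the population divisor S, keeping the statistic
#' smooth and matching large-S behavior).
#'
#' @inheritParams quantile_elicit
#' @return B x 2 array `(mean, sd)`, column-major (dual when `z` is dual).
#' @export
moment_elicit <- function(z, B, S) {
  if (S < 2) stop("moment elicitation needs S >= 2")
  d <- as_dual(z, if (is_dual(z)) dual_nP(z) else 0L)
  m <- dual_rowmeans(d, B, S)
  varp <- dual_rowvar(d, B, S, divisor = "n")
  sdd <- sqrt(varp + 1e-12)
  out <- dual_bind(m, sdd)
  if (is_dual(z)) out else dual_value(out)
}

#' Histogram elicitation
#'
#' Returns the samples themselves (no binning): the downstream discrepancy is
#' a set-based MMD, so binning would only discard information and gradients.
#' Optionally thins to at most `max_points` values with a deterministic stride.
#'
#' @param z length B*S array (numeric or dual).
#' @param max_points optional ceiling on the number of returned samples.
#' @return sample vector (dual when `z` is dual).
#' @export
histogram_elicit <- function(z, max_points = NULL) {
  n <- length(if (is_dual(z)) z$v else z)
  if (!is.null(max_points) && n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    z <- if (is_dual(z)) dual_sub(z, idx) else z[idx]
  }
  z
}

# Apply one plan entry's technique to its computed target.
elicit_statistic <- function(entry, z, B, S, hist_max = 1000L) {
  switch(entry$technique$kind,
    quantiles = list(values = quantile_elicit(z, B, S, entry$technique$p),
                     d = length(entry$technique$p), n = B),
    moments = list(values = moment_elicit(z, B, S), d = 2L, n = B),
    histogram = {
      h <- histogram_elicit(z, max_points = hist_max)
      list(values = h, d = 1L, n = length(if (is_dual(h)) h$v else h))
    }
  )
}
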