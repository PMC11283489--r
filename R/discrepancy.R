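# Discrepancy between model-implied and expert-elicited statistics: the biased
# squared maximum mean discrepancy with the energy kernel, combined across
# components as a weighted multi-objective loss.

#' Energy kernel
#'
#' `k(x, y) = -||x - y||` (Euclidean). Characteristic, hyperparameter-free;
#' with this kernel the biased squared MMD equals the energy distance.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar kernel value; `k(x, x) = 0`.
#' @export
energy_kernel <- function(x, y) {
  if (length(x) != length(y)) stop("energy kernel: dimension mismatch")
  -sqrt(sum((x - y)^2))
}

# Pairwise Euclidean distances between rows of a (n x d) and b (m x d).
# Computed from per-dimension differences (not the expanded inner-product
# form, which loses ~1e-8 to cancellation for nearby points); d <= 3 here.
pair_dist <- function(a, b) {
  d2 <- 0
  for (k in seq_len(ncol(a))) {
    dk <- outer(a[, k], b[, k], "-")
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Biased squared MMD with the energy kernel
#'
#' `MMD^2_b = mean k(x_i, x_j) + mean k(y_i, y_j) - 2 mean k(x_i, y_j)`.
#' Non-negative with the energy kernel (tiny negative floating-point values
#' are clamped to zero) and zero iff the two multisets coincide. When `x` is a
#' dual, the result is a dual scalar whose gradient flows through the model
#' side only (the expert side is data).
#'
#' @param x model-side sample set: numeric matrix (n x d, points in rows),
#'   numeric vector (d = 1), or a dual (with `n`, `d` supplied).
#' @param y expert-side sample set: numeric matrix (m x d) or vector.
#' @param n,d dimensions of `x` when `x` is a dual stored column-major.
#' @param kyy_mean optional precomputed expert-side term `mean k(y_i, y_j)`
#'   (constant across training epochs).
#' @return scalar (or dual scalar) squared discrepancy, >= 0.
#' @export
mmd2_biased <- function(x, y, n = NULL, d = NULL, kyy_mean = NULL) {
  if (is.null(dim(y))) y <- matrix(y, ncol = d %||% 1L)
  if (is_dual(x)) return(mmd2_dual(x, n, d %||% ncol(y), y, kyy_mean))
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(y))
  if (nrow(x) < 1 || nrow(y) < 1) stop("mmd2_biased: empty sample set")
  if (ncol(x) != ncol(y)) stop("mmd2_biased: dimension mismatch")
  kxx <- -pair_dist(x, x)
  kyy <- -pair_dist(y, y)
  kxy <- -pair_dist(x, y)
  val <- mean(kxx) + mean(kyy) - 2 * mean(kxy)
  if (val < -1e-10) val else max(val, 0)
}

# Dual version: x is a dual of length n*d (column-major n x d), y (m x d).
# The value uses exact norms; gradients use an epsilon-smoothed norm so the
# kernel's kink at coincident points contributes a zero subgradient.
# `kyy_mean` optionally supplies the (constant) expert-side term mean k(y,y'),
# which training precomputes once per component.
mmd2_dual <- function(x, n, d, y, kyy_mean = NULL) {
  P <- ncol(x$g)
  xm <- matrix(x$v, n, d)
  m <- nrow(y)
  dxx <- pair_dist(xm, xm)
  dxy <- pair_dist(xm, y)
  if (is.null(kyy_mean)) kyy_mean <- -mean(pair_dist(y, y))
  val <- -mean(dxx) + kyy_mean + 2 * mean(dxy)
  # gradient wrt x rows
  rxx <- sqrt(dxx^2 + 1e-12)
  rxy <- sqrt(dxy^2 + 1e-12)
  gx <- matrix(0, n, d)
  for (k in seq_len(d)) {
    diffxx <- outer(xm[, k], xm[, k], "-")      # x_a - x_j
    diffxy <- outer(xm[, k], y[, k], "-")       # x_a - y_j
    gx[, k] <- -(2 / n^2) * rowSums(diffxx / rxx) +
      (2 / (n * m)) * rowSums(diffxy / rxy)
  }
  gl <- numeric(P)
  for (p in seq_len(P)) gl[p] <- sum(gx * matrix(x$g[, p], n, d))
  v <- if (val < -1e-10) val else max(val, 0)
  new_dual(v, matrix(gl, 1))
}

#' Combine loss components into the total loss
#'
#' `L(lambda) = sum_m alpha_m L_m`, retaining the per-component values and
#' weights for diagnostics and dynamic weighting.
#'
#' @param losses numeric vector of component discrepancies L_m (>= 0).
#' @param weights numeric vector of weights alpha_m (>= 0); default all 1.
#' @param ids optional component ids.
#' @return list of class `"loss_report"` with `components` (data.frame: id,
#'   loss, weight) and `total`.
#' @export
total_loss <- function(losses, weights = rep(1, length(losses)), ids = NULL) {
  if (length(losses) < 1) stop("at least one loss component is required")
  if (length(weights) != length(losses)) stop("weights/losses length mismatch")
  if (any(weights < 0)) stop("negative loss weight")
  if (is.null(ids)) ids <- paste0("L", seq_along(losses))
  structure(list(components = data.frame(id = ids, loss = losses,
                                         weight = weights),
                 total = sum(weights * losses)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report> total =", format(x$total), "\n")
  print(x$components)
  invisible(x)
}

#' Dynamic weight averaging
#'
#' Multi-task weighting by learning speed: with per-component losses from the
#' last two epochs, the ratio `r_m = L_m(t-1) / L_m(t-2)` measures how slowly
#' component m is improving, and the weights are a temperature-softened
#' softmax of the ratios scaled to sum to M:
#' `alpha_m = M * exp(r_m / T) / sum exp(r_m' / T)`. With fewer than two
#' recorded epochs (or degenerate ratios) the weights are all 1.
#'
#' @param loss_history numeric matrix with one row per epoch and one column per
#'   component (at least the last two epochs).
#' @param temperature softmax temperature T (> 0), default 2.
#' @return numeric vector of weights summing to the number of components.
#' @export
dwa_weights <- function(loss_history, temperature = 2) {
  M <- ncol(loss_history)
  if (nrow(loss_history) < 2) return(rep(1, M))
  lprev <- loss_history[nrow(loss_history), ]
  lprev2 <- loss_history[nrow(loss_history) - 1, ]
  r <- ifelse(lprev2 > 0, lprev / lprev2, 1)
  r[!is.finite(r)] <- 1
  e <- pmax(exp((r - max(r)) / temperature), 1e-12) # keep weights positive
  M * e / sum(e)
}
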