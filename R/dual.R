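# Forward-mode dual numbers.
#
# A "dual" carries a value vector `v` (length n, possibly with array semantics
# managed by the caller) and a Jacobian `g` (n x P matrix) of partial
# derivatives with respect to P tangent directions -- here, the unconstrained
# hyperparameter vector. Forward mode is the right tool because P <= 14 in all
# shipped models while intermediate arrays can hold ~10^6 elements.
#
# P = 0 is a valid and useful degenerate case: the same simulation code then
# runs gradient-free (used by the expert oracle).

#' Construct a dual number array
#'
#' @param v numeric vector of values.
#' @param g numeric matrix of partial derivatives, `length(v)` rows and one
#'   column per tangent direction. Defaults to all zeros (a constant).
#' @param P number of tangent directions when `g` is not given.
#' @return an object of class `"dual"`.
#' @keywords internal
new_dual <- function(v, g = NULL, P = 0L) {
  v <- as.numeric(v)
  if (is.null(g)) g <- matrix(0, length(v), P)
  stopifnot(is.matrix(g), nrow(g) == length(v))
  structure(list(v = v, g = g), class = "dual")
}

is_dual <- function(x) inherits(x, "dual")

#' @keywords internal
dual_value <- function(x) if (is_dual(x)) x$v else as.numeric(x)

#' @keywords internal
dual_grad <- function(x) x$g

dual_nP <- function(x) ncol(x$g)

# Promote numeric to a constant dual with P tangents.
as_dual <- function(x, P) {
  if (is_dual(x)) x else new_dual(as.numeric(x), P = P)
}

# Recycle a length-1 dual (or shrink nothing) up to length n.
dual_recycle <- function(x, n) {
  if (length(x$v) == n) return(x)
  if (length(x$v) == 1L) {
    return(new_dual(rep(x$v, n), matrix(x$g, n, ncol(x$g), byrow = TRUE)))
  }
  stop("dual recycling only supports scalar-to-vector expansion")
}

align2 <- function(e1, e2) {
  P <- max(if (is_dual(e1)) dual_nP(e1) else 0L,
           if (is_dual(e2)) dual_nP(e2) else 0L)
  e1 <- as_dual(e1, P); e2 <- as_dual(e2, P)
  n <- max(length(e1$v), length(e2$v))
  list(x = dual_recycle(e1, n), y = dual_recycle(e2, n))
}

#' @export
Ops.dual <- function(e1, e2) {
  if (missing(e2)) { # unary
    if (.Generic == "-") return(new_dual(-e1$v, -e1$g))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for dual: ", .Generic)
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    return(get(.Generic)(dual_value(e1), dual_value(e2)))
  }
  a <- align2(e1, e2); x <- a$x; y <- a$y
  switch(.Generic,
    "+" = new_dual(x$v + y$v, x$g + y$g),
    "-" = new_dual(x$v - y$v, x$g - y$g),
    "*" = new_dual(x$v * y$v, x$g * y$v + y$g * x$v),
    "/" = new_dual(x$v / y$v, (x$g * y$v - y$g * x$v) / (y$v^2)),
    "^" = {
      if (is_dual(e2) && any(e2$g != 0))
        stop("dual exponent not supported")
      p <- y$v
      new_dual(x$v^p, x$g * (p * x$v^(p - 1)))
    },
    stop("unsupported op for dual: ", .Generic)
  )
}

#' @export
Math.dual <- function(x, ...) {
  switch(.Generic,
    exp  = new_dual(exp(x$v), x$g * exp(x$v)),
    log  = new_dual(log(x$v), x$g / x$v),
    sqrt = new_dual(sqrt(x$v), x$g * (0.5 / sqrt(x$v))),
    abs  = new_dual(abs(x$v), x$g * sign(x$v)),
    stop("unsupported math fn for dual: ", .Generic)
  )
}

#' @export
length.dual <- function(x) length(x$v)

#' @export
print.dual <- function(x, ...) {
  cat("<dual> n =", length(x$v), " P =", ncol(x$g), "\n")
  print(utils::head(x$v))
  invisible(x)
}

# ---- structural helpers -----------------------------------------------------

# Subset elements (gradient rows follow).
dual_sub <- function(x, idx) new_dual(x$v[idx], x$g[idx, , drop = FALSE])

dual_bind <- function(...) {
  xs <- list(...)
  new_dual(unlist(lapply(xs, `[[`, "v")), do.call(rbind, lapply(xs, `[[`, "g")))
}

dual_sum <- function(x) new_dual(sum(x$v), matrix(colSums(x$g), 1))

dual_mean <- function(x) new_dual(mean(x$v), matrix(colMeans(x$g), 1))

# Row means of x viewed as an (nr x nc) column-major matrix -> dual length nr.
dual_rowmeans <- function(x, nr, nc) {
  v <- rowMeans(matrix(x$v, nr, nc))
  P <- ncol(x$g)
  g <- matrix(0, nr, P)
  for (p in seq_len(P)) g[, p] <- rowMeans(matrix(x$g[, p], nr, nc))
  new_dual(v, g)
}

# x (n x k) column-major times constant matrix A (k x m) -> (n x m) column-major.
dual_matmul <- function(x, n, k, A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == k)
  v <- matrix(x$v, n, k) %*% A
  P <- ncol(x$g)
  g <- matrix(0, n * ncol(A), P)
  for (p in seq_len(P)) g[, p] <- as.numeric(matrix(x$g[, p], n, k) %*% A)
  new_dual(as.numeric(v), g)
}

# Clamp values; gradient is zeroed where the clamp is active.
dual_clip <- function(x, lo, hi) {
  act <- x$v < lo | x$v > hi
  v <- pmin(pmax(x$v, lo), hi)
  g <- x$g
  if (any(act)) g[act, ] <- 0
  new_dual(v, g)
}

# Logistic function with chain rule.
dual_plogis <- function(x) {
  p <- stats::plogis(x$v)
  new_dual(p, x$g * (p * (1 - p)))
}

# Row variance of x viewed as (nr x nc) column-major; divisor selectable.
dual_rowvar <- function(x, nr, nc, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  m <- dual_rowmeans(x, nr, nc)
  mfull <- dual_sub(m, rep.int(seq_len(nr), nc))
  d <- x - mfull
  ss <- dual_rowmeans(d * d, nr, nc)
  if (divisor == "n-1") ss * (nc / (nc - 1)) else ss
}
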