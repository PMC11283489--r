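# Hyperparameter vector: named entries, each unconstrained or positive.
# Positive entries are stored (and optimized) on the log scale; the natural
# scale is the exponential of the stored value.

#' Create a hyperparameter vector
#'
#' Holds the prior hyperparameters lambda that the method learns. Entries with
#' constraint `"positive"` (prior scales, Gamma concentration/rate, truncation
#' scales) are stored internally on the log scale so that optimization is
#' unconstrained; [to_natural()] exposes them on the natural scale.
#'
#' @param values named numeric vector of natural-scale values.
#' @param constraints character vector (same names/order) with entries
#'   `"unconstrained"` or `"positive"`.
#' @return an object of class `"hyperparameters"`.
#' @examples
#' h <- hyperparameters(c(mu0 = 0.12, sigma0 = 0.02),
#'                      c(mu0 = "unconstrained", sigma0 = "positive"))
#' to_natural(h)
#' @export
hyperparameters <- function(values, constraints) {
  nm <- names(values)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("hyperparameter names must be present and unique")
  constraints <- constraints[nm]
  if (any(is.na(constraints)) ||
      !all(constraints %in% c("unconstrained", "positive")))
    stop("unknown constraint tag; use 'unconstrained' or 'positive'")
  pos <- constraints == "positive"
  if (any(values[pos] <= 0))
    stop("positive-constrained hyperparameters must be > 0 on the natural scale")
  unc <- values
  unc[pos] <- log(values[pos])
  structure(list(names = nm, unconstrained = unname(unc),
                 constraint = unname(constraints)),
            class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat("<hyperparameters>\n")
  print(data.frame(name = x$names, natural = to_natural(x),
                   constraint = x$constraint, row.names = NULL))
  invisible(x)
}

#' @export
length.hyperparameters <- function(x) length(x$names)

#' Natural-scale view of a hyperparameter vector
#'
#' Positive-constrained entries are exponentiated; unconstrained entries pass
#' through unchanged.
#'
#' @param lambda a [hyperparameters()] object.
#' @return named numeric vector on the natural scale.
#' @export
to_natural <- function(lambda) {
  stopifnot(inherits(lambda, "hyperparameters"))
  v <- ifelse(lambda$constraint == "positive",
              exp(lambda$unconstrained), lambda$unconstrained)
  stats::setNames(v, lambda$names)
}

#' Unconstrained (internal) representation
#' @param lambda a [hyperparameters()] object.
#' @return named numeric vector on the unconstrained scale (log for positive
#'   entries).
#' @export
to_unconstrained <- function(lambda) {
  stats::setNames(lambda$unconstrained, lambda$names)
}

# Replace the unconstrained values (e.g. after an SGD step).
set_unconstrained <- function(lambda, u) {
  stopifnot(length(u) == length(lambda$unconstrained))
  lambda$unconstrained <- as.numeric(u)
  lambda
}

# Natural-scale duals seeded with identity tangents on the unconstrained scale.
# Returns a named list of scalar duals (P = length(lambda)).
natural_duals <- function(lambda) {
  P <- length(lambda$names)
  out <- vector("list", P)
  names(out) <- lambda$names
  for (i in seq_len(P)) {
    g <- matrix(0, 1, P); g[1, i] <- 1
    d <- new_dual(lambda$unconstrained[i], g)
    out[[i]] <- if (lambda$constraint[i] == "positive") exp(d) else d
  }
  out
}
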