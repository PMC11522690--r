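# Minimal neural-network plumbing shared by the representation block and
# the readout heads: shifted-softplus nonlinearity, seeded fan-in weight
# initialization, and an Adam optimizer over nested parameter lists.
# Gradients are hand-derived in representation.R / readout.R; a
# finite-difference check in the test suite guards the algebra.

#' Shifted softplus nonlinearity
#'
#' `ssp(x) = ln(0.5 e^x + 0.5) = softplus(x) - ln 2`; smooth, zero at the
#' origin, with derivative `sigmoid(x)`. Evaluated in a numerically stable
#' form for large |x|.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`.
#' @export
ssp <- function(x) {
  # softplus(x) = max(x, 0) + log1p(exp(-|x|))
  pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
}

#' Derivative of the shifted softplus (the logistic sigmoid)
#' @param x numeric.
#' @return sigmoid(x).
#' @keywords internal
ssp_grad <- function(x) 1 / (1 + exp(-x))

# Seeded uniform fan-in initializer: W ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
# Consumes the current RNG stream; callers set the seed once per model.
.init_dense <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

# Zero-filled structure mirroring a nested parameter list.
.zeros_like <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

# Elementwise combination of two structurally identical nested lists.
.map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(.map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

# Adam state for a parameter structure.
.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

# One Adam step; returns list(params, state).
.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- .map2_params(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  params <- .map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# rowsum() that keeps empty groups as zero rows (rowsum() drops them).
.rowsum_full <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  if (nrow(x) > 0L) {
    rs <- rowsum(x, group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}
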