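# Internal numeric helpers: seeded streams, weighted summaries, Box-Cox,
# Gauss-Hermite nodes.

# Deterministic child seed from a master seed and a stage label.  Polynomial
# string hash folded into [0, 2^31 - 2]; keeps independent streams per stage
# and per (scenario, strategy) without a global RNG dependency.
child_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(master_seed) + h) %% 2147483647)
}

# Weighted mean with NA-safe zero-weight guard.
wmean <- function(x, w) {
  sum(w * x) / sum(w)
}

# Population-style weighted variance (denominator sum of weights).
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Weighted quantiles by linear interpolation of the weighted ECDF
# (Harrell-Davis not needed; this matches type-7 in the equal-weight case
# asymptotically and is exact at the atoms for degenerate data).
wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Box-Cox transform on the grid lambda in [0, 1]; lambda = 0 is the log.
box_cox <- function(y, lambda) {
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

# Inverse Box-Cox.  Negative bases (possible far in the lower tail when
# lambda > 0) are clamped to zero; the caller counts clamps.
inv_box_cox <- function(t, lambda) {
  if (lambda == 0) {
    exp(t)
  } else {
    base <- pmax(lambda * t + 1, 0)
    base^(1 / lambda)
  }
}

n_neg_base <- function(t, lambda) {
  if (lambda == 0) 0L else sum(lambda * t + 1 < 0)
}

# Gauss-Hermite nodes/weights recast for E[f(Z)], Z ~ N(0,1):
# E f(Z) = sum(w_std * f(x_std)).
gauss_hermite_std <- function(n_nodes = 30L) {
  gh <- pracma::gaussHermite(n_nodes)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
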