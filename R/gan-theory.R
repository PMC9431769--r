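#' @include utils.R
NULL

## Small closed-form helpers for the GAN value function on toy discrete
## distributions.  They are not used by training; they exist to make the
## equilibrium theory checkable: the pointwise maximizer of
## a*log(y) + b*log(1-y) is y = a/(a+b), and at the optimal discriminator
## the generator criterion equals -log 4 + 2*JS(p_data || p_g), minimized
## exactly when the generator matches the data distribution.

#' Optimal discriminator value for given densities
#'
#' For real-data density value `a` and generator density value `b` at a
#' point, the discriminator output maximizing
#' `a log(y) + b log(1 - y)` is `a / (a + b)`; at `a = b` this is 1/2,
#' the adversarial equilibrium.
#'
#' @param a,b nonnegative density values (not both zero; vectorized).
#' @return `a / (a + b)`.
#' @examples
#' optimalDiscriminator(1, 1)   # 0.5
#' optimalDiscriminator(1, 0)   # 1
#' @export
optimalDiscriminator <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    emgStop("density values must be nonnegative", "emgGAN_value_error")
  if (any(a + b == 0))
    emgStop("a + b must be positive", "emgGAN_value_error")
  a / (a + b)
}

checkDistribution <- function(p, tol = 1e-9) {
  if (any(p < 0))
    emgStop("probabilities must be nonnegative", "emgGAN_value_error")
  if (abs(sum(p) - 1) > tol)
    emgStop("distribution does not sum to 1", "emgGAN_value_error")
  p
}

## KL(p || q) with natural log; 0 log 0 = 0 by continuity
klDivergence <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' Jensen-Shannon divergence of two discrete distributions
#'
#' `JS(p || q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`,
#' natural logarithm. Symmetric, zero iff `p == q`, and equal to `log 2`
#' for distributions with disjoint support.
#'
#' @param p,q probability vectors on a common finite support (each
#'   summing to 1 within `tol`).
#' @param tol normalization tolerance (default 1e-9).
#' @return nonnegative scalar in `[0, log 2]`.
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))  # log(2)
#' @export
jsDivergence <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q))
    emgStop("distributions must share a support", "emgGAN_value_error")
  checkDistribution(p, tol)
  checkDistribution(q, tol)
  m <- (p + q) / 2
  0.5 * klDivergence(p, m) + 0.5 * klDivergence(q, m)
}

#' Generator criterion at the optimal discriminator
#'
#' `C(G) = -log 4 + 2 * JS(p_data || p_g)`: the virtual training
#' criterion of the generator when the discriminator is optimal. Its
#' global minimum is `-log 4`, attained exactly when the generator
#' distribution equals the data distribution; for disjoint supports it is
#' 0.
#'
#' @param pData,pG probability vectors on a common finite support.
#' @param tol normalization tolerance.
#' @return scalar `>= -log 4`.
#' @examples
#' cOfG(c(0.5, 0.5), c(0.5, 0.5))  # -log(4)
#' @export
cOfG <- function(pData, pG, tol = 1e-9) {
  -log(4) + 2 * jsDivergence(pData, pG, tol)
}
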