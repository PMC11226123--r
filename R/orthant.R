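#' Upper-orthant probability of a standard bivariate normal
#'
#' Computes \eqn{P(L_1 > \tau, L_2 > \tau)} where \eqn{(L_1, L_2)} is
#' standard bivariate normal with correlation \code{rho}. This is the
#' probability that both members of a pair exceed the liability threshold,
#' i.e. the expected proportion of concordant-affected pairs under the
#' liability-threshold model.
#'
#' The integral is evaluated by adaptive one-dimensional quadrature of the
#' conditional-normal integrand,
#' \deqn{\int_\tau^\infty \phi(x)\, \bar\Phi\!\left(\frac{\tau - \rho x}
#'   {\sqrt{1-\rho^2}}\right) dx,}
#' which is smooth for \eqn{|\rho| < 1}. The degenerate cases
#' \eqn{\rho = \pm 1} use closed forms (comonotone and antithetic
#' liabilities).
#'
#' @param tau liability threshold in standard-normal units.
#' @param rho latent correlation, in \eqn{[-1, 1]}.
#' @param rel.tol relative accuracy target passed to [stats::integrate()].
#' @return A single probability.
#' @examples
#' bvn_upper(0, 0)    # 0.25
#' bvn_upper(0, 1)    # 0.5
#' @export
bvn_upper <- function(tau, rho, rel.tol = 1e-12) {
  stopifnot(is.finite(tau), is.finite(rho))
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  if (rho >= 1) return(stats::pnorm(tau, lower.tail = FALSE))
  if (rho <= -1) return(max(0, 1 - 2 * stats::pnorm(tau)))
  if (rho == 0) return(stats::pnorm(tau, lower.tail = FALSE)^2)
  s <- sqrt(1 - rho^2)
  f <- function(x) {
    stats::dnorm(x) * stats::pnorm((tau - rho * x) / s, lower.tail = FALSE)
  }
  out <- stats::integrate(f, lower = tau, upper = Inf,
                          rel.tol = rel.tol, abs.tol = 1e-14,
                          subdivisions = 400L)
  min(max(out$value, 0), 1)
}

#' Cell probabilities of a symmetrized 2x2 concordance table
#'
#' Probabilities of the four outcome cells for an exchangeable pair of
#' binary indicators under the liability-threshold model: each member is
#' affected when its standard-normal liability exceeds the shared threshold
#' \code{tau}, and the two liabilities have correlation \code{rho}.
#'
#' Because the pair is exchangeable (a single threshold for both members),
#' the off-diagonal cells are equal: \code{p01 == p10}.
#'
#' @inheritParams bvn_upper
#' @return Named numeric vector \code{c(p00, p01, p10, p11)} summing to 1.
#' @examples
#' cell_probabilities(rho = 0, tau = 0)
#' @export
cell_probabilities <- function(rho, tau) {
  p11 <- bvn_upper(tau, rho)
  p1 <- stats::pnorm(tau, lower.tail = FALSE)  # marginal P(affected)
  p01 <- p1 - p11
  p01 <- min(max(p01, 0), 1)
  p00 <- 1 - 2 * p01 - p11
  p00 <- min(max(p00, 0), 1)
  c(p00 = p00, p01 = p01, p10 = p01, p11 = p11)
}
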