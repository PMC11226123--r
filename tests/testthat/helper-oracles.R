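# Independent oracles used across the suite. These never call the code
# paths they check: the orthant oracle is 2-D quadrature of the bivariate
# normal density (pracma::integral2), and the tetrachoric oracle is a
# coarse-to-fine grid search over (rho, tau).

# reference values computed before the build with an independent
# implementation (scipy.stats.norm.ppf / scipy.integrate.dblquad)
REF_TAU_017 <- 0.9541652531461943      # qnorm oracle for prevalence 0.17
REF_P11_R05 <- 0.06900670149747938     # P(L1>0.9542, L2>0.9542 | rho=0.5)

# orthant probability by a 2-D Gauss-Legendre product rule on the
# bivariate normal density (independent of the package's conditional
# 1-D adaptive quadrature)
orthant_quad <- function(tau, rho, upper = 9, nodes = 240) {
  g <- pracma::gaussLegendre(nodes, tau, upper)
  s <- 1 - rho^2
  X <- outer(g$x, g$x, function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * s)) / (2 * pi * sqrt(s)))
  as.numeric(t(g$w) %*% X %*% g$w)
}

# multinomial log-likelihood of a symmetrized 2x2 table
table_loglik <- function(n, rho, tau) {
  p <- cell_probabilities(rho, tau)
  sum(n * log(pmax(p, 1e-300)))
}

# coarse-to-fine grid search: 101x101 start grid over the full ranges,
# then two 41x41 zooms around the running argmax (final rho resolution
# about 2e-4, independent of the quasi-Newton path used by the package)
grid_tetrachoric <- function(n, rho_range = c(-0.99, 0.99),
                             tau_range = c(-3, 3)) {
  best <- c(rho = 0, tau = 0, ll = -Inf)
  ranges <- list(rho = rho_range, tau = tau_range)
  sizes <- c(101, 41, 41)
  for (stage in 1:3) {
    rhos <- seq(ranges$rho[1], ranges$rho[2], length.out = sizes[stage])
    taus <- seq(ranges$tau[1], ranges$tau[2], length.out = sizes[stage])
    ll <- outer(rhos, taus, Vectorize(function(r, t) table_loglik(n, r, t)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(rho = rhos[idx[1]], tau = taus[idx[2]], ll = max(ll))
    dr <- diff(ranges$rho) / (sizes[stage] - 1)
    dt <- diff(ranges$tau) / (sizes[stage] - 1)
    ranges$rho <- pmax(pmin(best["rho"] + c(-2, 2) * dr, 0.99), -0.99)
    ranges$tau <- best["tau"] + c(-2, 2) * dt
  }
  best
}

# exact concordance table scaled to N pairs for a given (rho, tau)
exact_table <- function(rho, tau, N, group = "same_sex") {
  p <- cell_probabilities(rho, tau)
  data.frame(group = group, stratum = "all",
             n00 = p[1] * N, n01 = p[2] * N, n10 = p[3] * N,
             n11 = p[4] * N, n_pairs = N, stringsAsFactors = FALSE)
}

# two-group exact tables for an ACE truth under a Weinberg adjustment
exact_ace_tables <- function(a2, c2, adj, tau, N) {
  rbind(exact_table(adj$gamma * a2 + c2, tau, N, "same_sex"),
        exact_table(0.5 * a2 + c2, tau, N, "opposite_sex"))
}
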