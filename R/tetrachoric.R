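RHO_MAX <- 0.9999  # interior bound on |rho|; estimates at the bound are boundary fits

#' Maximum-likelihood tetrachoric correlation from a 2x2 table
#'
#' Estimates the latent bivariate-normal (tetrachoric) correlation
#' \eqn{\rho} and shared liability threshold \eqn{\tau} from a 2x2
#' concordance table by maximizing the multinomial log-likelihood
#' \eqn{\sum_{ij} n_{ij} \log p_{ij}(\rho, \tau)}, with cell probabilities
#' from [cell_probabilities()]. A single threshold is used because tables
#' from exchangeable pairs are symmetrized (see [aggregate_pairs()]).
#'
#' Optimization is bounded quasi-Newton (L-BFGS-B) on
#' \eqn{(\mathrm{atanh}\,\rho, \tau)}, keeping \eqn{\rho} interior. The
#' standard error of \eqn{\rho} comes from the numerically observed
#' information, mapped back from the atanh scale by the delta method.
#' Degenerate tables (all mass in one cell, or no discordant pairs) give a
#' boundary estimate with a warning and no standard error.
#'
#' @param table a one-row data frame with columns \code{n00}, \code{n01},
#'   \code{n10}, \code{n11} (as produced by [aggregate_pairs()]) or a
#'   numeric vector of the four counts in that order. Fractional counts
#'   are allowed.
#' @return An object of class \code{"tetrachoric_fit"}: a list with
#'   elements \code{rho}, \code{tau}, \code{se_rho}, \code{se_tau},
#'   \code{loglik}, \code{n}, \code{converged}, \code{boundary}.
#' @examples
#' fit_tetrachoric(c(25, 25, 25, 25))   # rho ~ 0, tau ~ 0
#' @export
fit_tetrachoric <- function(table) {
  n <- as_cell_counts(table)
  N <- sum(n)
  if (N < 2) stop("need at least two pairs to estimate a correlation")
  if (sum(n > 0) < 2) {
    warning("degenerate table (all mass in one cell); boundary estimate")
    rho <- if (n["n11"] > 0 || n["n00"] > 0) RHO_MAX else -RHO_MAX
    tau <- stats::qnorm(1 - min(max(marginal_p(n), 1e-8), 1 - 1e-8))
    return(new_tetra(rho, tau, NA_real_, NA_real_,
                     tetra_loglik(n, rho, tau), N,
                     converged = TRUE, boundary = TRUE))
  }
  phat <- marginal_p(n)
  start <- c(z = 0, tau = stats::qnorm(1 - min(max(phat, 1e-4), 1 - 1e-4)))
  negll <- function(par) -tetra_loglik(n, tanh(par[1]), par[2])
  zmax <- atanh(RHO_MAX)
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(-zmax, -6), upper = c(zmax, 6),
                      control = list(factr = 1e6, maxit = 500))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, method = "L-BFGS-B",
                         lower = c(-zmax, -6), upper = c(zmax, 6),
                         control = list(factr = 1e8, maxit = 500))
    if (opt2$value <= opt$value) opt <- opt2
  }
  rho <- tanh(opt$par[1]); tau <- opt$par[2]
  boundary <- abs(rho) >= RHO_MAX - 1e-6
  se_rho <- se_tau <- NA_real_
  if (!boundary) {
    H <- try(stats::optimHess(opt$par, negll), silent = TRUE)
    V <- if (inherits(H, "try-error")) NULL else try(solve(H), silent = TRUE)
    if (!is.null(V) && !inherits(V, "try-error") && all(diag(V) > 0)) {
      se_rho <- (1 - rho^2) * sqrt(V[1, 1])  # d tanh(z)/dz = 1 - rho^2
      se_tau <- sqrt(V[2, 2])
    }
  } else {
    warning("tetrachoric estimate at the boundary |rho| = ", RHO_MAX,
            "; standard error unavailable")
  }
  new_tetra(rho, tau, se_rho, se_tau, -opt$value, N,
            converged = opt$convergence == 0, boundary = boundary)
}

marginal_p <- function(n) {
  # symmetrized share of affected members
  (n["n01"] + n["n10"] + 2 * n["n11"]) / (2 * sum(n))
}

tetra_loglik <- function(n, rho, tau) {
  p <- cell_probabilities(rho, tau)
  sum(n * log(pmax(p, 1e-300)))
}

new_tetra <- function(rho, tau, se_rho, se_tau, loglik, n, converged,
                      boundary) {
  structure(list(rho = unname(rho), tau = unname(tau),
                 se_rho = unname(se_rho), se_tau = unname(se_tau),
                 loglik = unname(loglik), n = unname(n),
                 converged = converged, boundary = boundary),
            class = "tetrachoric_fit")
}

#' @export
print.tetrachoric_fit <- function(x, digits = 4, ...) {
  cat("Tetrachoric correlation (liability-threshold ML)\n")
  cat("  rho =", format(x$rho, digits = digits),
      if (!is.na(x$se_rho)) paste0("(SE ", format(x$se_rho, digits = 3), ")"),
      "\n")
  cat("  tau =", format(x$tau, digits = digits),
      if (!is.na(x$se_tau)) paste0("(SE ", format(x$se_tau, digits = 3), ")"),
      "\n")
  cat("  log-likelihood =", format(x$loglik, digits = digits),
      " N =", format(x$n), "\n")
  if (x$boundary) cat("  note: estimate at parameter-space boundary\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.tetrachoric_fit <- function(object, ...) {
  c(rho = object$rho, tau = object$tau)
}

#' @export
logLik.tetrachoric_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n, class = "logLik")
}

#' Tetrachoric correlations for every group and stratum
#'
#' Convenience wrapper fitting [fit_tetrachoric()] to each row of an
#' aggregated concordance-table data frame.
#'
#' @param tables output of [aggregate_pairs()].
#' @return A tidy data frame: group, stratum, rho, se_rho, tau, n_pairs,
#'   converged.
#' @export
tetrachoric_by_group <- function(tables) {
  stopifnot(is.data.frame(tables), nrow(tables) >= 1)
  rows <- lapply(seq_len(nrow(tables)), function(i) {
    f <- fit_tetrachoric(tables[i, , drop = FALSE])
    data.frame(group = tables$group[i], stratum = tables$stratum[i],
               rho = f$rho, se_rho = f$se_rho, tau = f$tau,
               n_pairs = tables$n_pairs[i], converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
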