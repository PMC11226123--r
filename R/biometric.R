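#' Fit a liability-threshold ACE/ADE model to twin or twin-sibling pairs
#'
#' Joint maximum-likelihood variance decomposition of a binary phenotype
#' from groups of pairs with different genetic relatedness. The expected
#' liability correlation in group \eqn{g} is
#' \eqn{r_g = \kappa_g a^2 + c^2} (ACE) or
#' \eqn{r_g = \kappa_g a^2 + \delta_g d^2} (ADE), with the same-sex group's
#' \eqn{\kappa} set to the Weinberg-mixture value \eqn{\gamma} (see
#' [weinberg()]) because that group mixes MZ and DZ pairs of unknown
#' zygosity. Cell probabilities of each group's 2x2 concordance table come
#' from [cell_probabilities()] and the summed multinomial log-likelihood is
#' maximized over the path coefficients \eqn{(a, c)} (or \eqn{(a, d)}) and
#' the threshold \eqn{\tau}.
#'
#' Variance components are squares of path coefficients, so they are
#' non-negative by construction and \eqn{e^2 = 1 - a^2 - c^2} completes the
#' standardization identity exactly. Standard errors are delta-method
#' transforms of the observed information in \eqn{(a, c, \tau)}; 95\% Wald
#' intervals are reported on the squared scale, truncated to \eqn{[0,1]}.
#' When a component estimate sits at the zero boundary its Wald SE is
#' unreliable and the fit flags it; [confint.biometric_fit()] offers
#' profile-likelihood intervals as an alternative.
#'
#' @param data either pair-level records (a data frame with columns
#'   \code{group}, \code{pheno_1}, \code{pheno_2}; see [read_pairs()] and
#'   [simulate_pairs()]) or an aggregated concordance-table data frame from
#'   [aggregate_pairs()].
#' @param model \code{"ACE"}, \code{"ADE"}, or \code{"AE"} (ACE with the
#'   shared-environment component fixed at zero).
#' @param design \code{"twin"} compares same-sex with opposite-sex twin
#'   pairs; \code{"twin_sibling"} compares same-sex twins with same-sex
#'   non-twin sibling pairs (the design used for sex-specific fits, where
#'   no opposite-sex group exists within a sex).
#' @param gamma the same-sex genetic correlation: \code{NULL} (computed
#'   from the same-sex/opposite-sex pair counts in \code{data} via
#'   [weinberg()]), a number in \eqn{[0.5, 1]}, or a [weinberg()] object.
#' @param sibling_c shared-environment coefficient for sibling pairs
#'   (default 1; lower values encode that non-twin siblings may share less
#'   environment).
#' @param tau_by_group if \code{TRUE}, estimate a separate threshold per
#'   group instead of one shared threshold.
#' @return An object of class \code{"biometric_fit"} with components
#'   \code{a2}, \code{c2_or_d2}, \code{e2}, standard errors, 95\% CIs,
#'   \code{tau}, \code{loglik}, \code{gamma}, \code{n_pairs_by_group},
#'   \code{converged} and boundary flags. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{vcov},
#'   \code{confint}.
#' @examples
#' d <- simulate_pairs(n_mz = 2000, n_dz = 4000, a2 = 0.6, c2 = 0.1,
#'                     prevalence = 0.17, seed = 7)
#' fit <- fit_biometric(d)
#' coef(fit)
#' @export
fit_biometric <- function(data, model = c("ACE", "ADE", "AE"),
                          design = c("twin", "twin_sibling"),
                          gamma = NULL, sibling_c = 1,
                          tau_by_group = FALSE) {
  model <- match.arg(model)
  design <- match.arg(design)
  tables <- if (all(c("n00", "n01", "n10", "n11") %in% names(data))) data
            else aggregate_pairs(data)
  if (!is.null(tables$stratum) && length(unique(tables$stratum)) > 1)
    stop("multiple strata in input; use fit_stratified()")

  use_groups <- switch(design,
                       twin = c("same_sex", "opposite_sex"),
                       twin_sibling = c("same_sex", "sibling"))
  tb <- tables[tables$group %in% use_groups, , drop = FALSE]
  if (length(unique(tb$group)) < 2)
    stop("design ", dQuote(design), " needs groups ",
         paste(use_groups, collapse = " and "),
         " but found: ", paste(unique(tables$group), collapse = ", "),
         if (design == "twin")
           ". For single-sex data use design = \"twin_sibling\"." else ".")

  adj <- resolve_gamma(gamma, tables)
  co <- group_coefficients(adj, sibling_c = sibling_c)
  co <- co[match(tb$group, co$group), , drop = FALSE]
  if (length(unique(co$kappa)) < 2)
    stop("all groups share the same genetic correlation (gamma = 0.5?); ",
         "a2 is not identifiable")

  counts <- lapply(seq_len(nrow(tb)),
                   function(i) as_cell_counts(tb[i, , drop = FALSE]))
  G <- nrow(tb)
  n_tau <- if (tau_by_group) G else 1L
  fix_q <- model == "AE"
  lik_model <- if (model == "ADE") "ADE" else "ACE"

  group_r <- function(a, q) {
    a2 <- a^2; q2 <- q^2
    vapply(seq_len(G), function(g)
      expected_pair_correlation(lik_model, a2, q2, kappa = co$kappa[g],
                                delta = co$delta[g], c_coef = co$c_coef[g]),
      numeric(1))
  }
  negll <- function(par) {
    a <- par[1]; q <- if (fix_q) 0 else par[2]
    taus <- par[(if (fix_q) 2 else 3):length(par)]
    if (a^2 + q^2 > 1) return(1e10 + 1e10 * (a^2 + q^2 - 1))
    r <- group_r(a, q)
    ll <- 0
    for (g in seq_len(G)) {
      tau_g <- if (tau_by_group) taus[g] else taus[1]
      p <- cell_probabilities(r[g], tau_g)
      ll <- ll + sum(counts[[g]] * log(pmax(p, 1e-300)))
    }
    -ll
  }

  phat <- vapply(counts, marginal_p, numeric(1))
  tau0 <- stats::qnorm(1 - min(max(mean(phat), 1e-4), 1 - 1e-4))
  start <- c(a = 0.6, if (!fix_q) c(q = 0.3), rep(tau0, n_tau))
  lower <- c(0, if (!fix_q) 0, rep(-6, n_tau))
  upper <- c(1, if (!fix_q) 1, rep(6, n_tau))
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e7, maxit = 1000))
  if (opt$convergence != 0) {
    # line-search failures near the boundary: restart from the best point
    opt2 <- stats::optim(opt$par, negll, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(factr = 1e9, maxit = 1000))
    if (opt2$value <= opt$value) opt <- opt2
  }

  a <- unname(opt$par[1])
  q <- if (fix_q) 0 else unname(opt$par[2])
  taus <- unname(opt$par[(if (fix_q) 2 else 3):length(opt$par)])
  a2 <- a^2; q2 <- q^2; e2 <- 1 - a2 - q2
  boundary <- c(a2 = a < 0.02, c2_or_d2 = !fix_q && q < 0.02)

  se <- c(a2 = NA_real_, c2_or_d2 = NA_real_)
  V <- NULL
  H <- try(stats::optimHess(opt$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Vtry <- try(solve(H), silent = TRUE)
    if (!inherits(Vtry, "try-error") && all(diag(Vtry) > 0)) {
      V <- Vtry
      se["a2"] <- 2 * a * sqrt(V[1, 1])
      if (!fix_q) se["c2_or_d2"] <- 2 * q * sqrt(V[2, 2])
    }
  }
  ci <- function(est, s) {
    if (is.na(s)) return(c(NA_real_, NA_real_))
    pmin(pmax(est + c(-1, 1) * stats::qnorm(0.975) * s, 0), 1)
  }

  structure(list(
    model = model, design = design,
    a2 = a2, c2_or_d2 = q2, e2 = e2,
    se_a2 = unname(se["a2"]), se_c2_or_d2 = unname(se["c2_or_d2"]),
    ci95_a2 = ci(a2, se["a2"]), ci95_c2_or_d2 = ci(q2, se["c2_or_d2"]),
    tau = taus, tau_by_group = tau_by_group,
    loglik = -opt$value,
    gamma = adj$gamma, p_mz = adj$p_mz,
    delta_same_sex = adj$delta_same_sex,
    sibling_c = sibling_c,
    groups = tb$group,
    n_pairs_by_group = stats::setNames(
      vapply(counts, sum, numeric(1)), tb$group),
    coefficients_table = co,
    counts = counts,
    paths = c(a = a, q = q),
    vcov_paths = V,
    boundary = boundary,
    converged = opt$convergence == 0
  ), class = "biometric_fit")
}

resolve_gamma <- function(gamma, tables) {
  if (inherits(gamma, "weinberg")) return(gamma)
  if (is.numeric(gamma)) {
    stopifnot(length(gamma) == 1, gamma >= 0.5, gamma <= 1)
    p_mz <- 2 * gamma - 1
    return(list(gamma = gamma, p_mz = p_mz,
                delta_same_sex = p_mz + 0.25 * (1 - p_mz)))
  }
  if (!is.null(gamma)) stop("'gamma' must be NULL, numeric, or a weinberg object")
  n_ss <- sum(tables$n_pairs[tables$group == "same_sex"])
  n_os <- sum(tables$n_pairs[tables$group == "opposite_sex"])
  if (is.na(n_ss) || n_ss < 1 || is.na(n_os) || n_os < 1)
    stop("cannot derive gamma: need same_sex and opposite_sex pair counts ",
         "(supply 'gamma' explicitly, e.g. for twin_sibling designs)")
  weinberg(n_ss, n_os)
}

component_label <- function(model) if (model == "ADE") "d2" else "c2"

#' @export
print.biometric_fit <- function(x, digits = 3, ...) {
  lab <- component_label(x$model)
  cat("Liability-threshold ", x$model, " model (", x$design,
      " design)\n", sep = "")
  cat("  gamma (same-sex genetic correlation):",
      format(x$gamma, digits = 4), "\n")
  est <- c(x$a2, x$c2_or_d2, x$e2)
  names(est) <- c("a2", lab, "e2")
  print(round(est, digits))
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.biometric_fit <- function(object, ...) {
  stats::setNames(c(object$a2, object$c2_or_d2, object$e2),
                  c("a2", component_label(object$model), "e2"))
}

#' @export
logLik.biometric_fit <- function(object, ...) {
  df <- length(object$paths) - (object$model == "AE") +
    length(object$tau)
  structure(object$loglik, df = df,
            nobs = sum(object$n_pairs_by_group), class = "logLik")
}

#' @export
vcov.biometric_fit <- function(object, ...) {
  if (is.null(object$vcov_paths)) return(NULL)
  object$vcov_paths
}

#' @export
summary.biometric_fit <- function(object, ...) {
  lab <- component_label(object$model)
  tab <- data.frame(
    component = c("a2", lab, "e2"),
    estimate = c(object$a2, object$c2_or_d2, object$e2),
    se = c(object$se_a2, object$se_c2_or_d2, NA),
    ci_lo = c(object$ci95_a2[1], object$ci95_c2_or_d2[1], NA),
    ci_hi = c(object$ci95_a2[2], object$ci95_c2_or_d2[2], NA),
    boundary = c(object$boundary, FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(fit = object, table = tab), class = "summary.biometric_fit")
}

#' @export
print.summary.biometric_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nComponents:\n")
  print(x$table, digits = digits, row.names = FALSE)
  if (any(x$table$boundary, na.rm = TRUE))
    cat("note: component(s) at the zero boundary; Wald SEs unreliable,",
        "consider confint(fit, type = \"profile\")\n")
  cat("pairs per group:",
      paste(names(x$fit$n_pairs_by_group),
            round(x$fit$n_pairs_by_group), collapse = ", "), "\n")
  invisible(x)
}

#' Confidence intervals for variance components
#'
#' Wald intervals on the squared-component scale (default), or
#' profile-likelihood intervals that invert the likelihood-ratio statistic
#' and remain valid when a component sits near its zero boundary.
#'
#' @param object a [fit_biometric()] result.
#' @param parm components to report (\code{"a2"}, \code{"c2_or_d2"}).
#' @param level confidence level.
#' @param type \code{"wald"} or \code{"profile"}.
#' @param ... unused.
#' @export
confint.biometric_fit <- function(object, parm = c("a2", "c2_or_d2"),
                                  level = 0.95,
                                  type = c("wald", "profile"), ...) {
  type <- match.arg(type)
  parm <- match.arg(parm, several.ok = TRUE)
  if (object$model == "AE") parm <- setdiff(parm, "c2_or_d2")
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  if (type == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    for (p in parm) {
      est <- object[[p]]
      s <- object[[paste0("se_", p)]]
      if (!is.na(s)) out[p, ] <- pmin(pmax(est + c(-1, 1) * z * s, 0), 1)
    }
    return(out)
  }
  for (p in parm) out[p, ] <- profile_ci(object, p, level)
  out
}

# profile-likelihood CI by inverting the LR statistic for one squared
# component, re-maximizing over the other parameters at each fixed value
profile_ci <- function(fit, parm, level) {
  crit <- stats::qchisq(level, df = 1) / 2
  which_path <- if (parm == "a2") 1L else 2L
  co <- fit$coefficients_table
  counts <- fit$counts
  G <- length(counts)
  lik_model <- if (fit$model == "ADE") "ADE" else "ACE"
  pll <- function(value) {
    fixed <- sqrt(value)
    obj <- function(par) {
      free <- par[1]
      a <- if (which_path == 1) fixed else free
      q <- if (which_path == 1) free else fixed
      taus <- par[-1]
      if (a^2 + q^2 > 1) return(1e10)
      ll <- 0
      for (g in seq_len(G)) {
        r <- expected_pair_correlation(lik_model, a^2, q^2,
                                       kappa = co$kappa[g],
                                       delta = co$delta[g],
                                       c_coef = co$c_coef[g])
        tau_g <- if (fit$tau_by_group) taus[g] else taus[1]
        p <- cell_probabilities(r, tau_g)
        ll <- ll + sum(counts[[g]] * log(pmax(p, 1e-300)))
      }
      -ll
    }
    other <- unname(fit$paths[-which_path])
    start <- c(max(other, 1e-3), fit$tau)
    o <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, rep(-6, length(fit$tau))),
                      upper = c(1, rep(6, length(fit$tau))),
                      control = list(factr = 1e6))
    -o$value
  }
  llmax <- fit$loglik
  dev <- function(v) llmax - pll(v) - crit
  est <- fit[[parm]]
  lo <- if (est <= 1e-8 || dev(0) <= 0) 0 else
    stats::uniroot(dev, c(0, est), tol = 1e-5)$root
  hi <- if (dev(min(1, est + 0.9999 * (1 - est))) < 0) 1 else
    stats::uniroot(dev, c(est, 1), tol = 1e-5)$root
  c(lo, hi)
}
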