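#' Weinberg-rule adjustment for unknown zygosity
#'
#' When zygosity is unobserved, opposite-sex twin pairs are necessarily
#' dizygotic, while the same-sex group mixes MZ and DZ pairs. Assuming DZ
#' co-twin sexes assort independently, the number of same-sex DZ pairs
#' equals the number of opposite-sex pairs, so the MZ proportion among
#' same-sex pairs is
#' \deqn{p_{MZ} = (N_{ss} - N_{os}) / N_{ss},}
#' and the genetic correlation assumed for the same-sex group is the
#' mixture
#' \deqn{\gamma = p_{MZ} \cdot 1 + (1 - p_{MZ}) \cdot 0.5
#'       = (N_{ss} - N_{os})/N_{ss} + 0.5\, N_{os}/N_{ss}.}
#' The analogous dominance mixture is
#' \eqn{\delta_{ss} = p_{MZ} + 0.25 (1 - p_{MZ})}.
#'
#' @param n_same_sex,n_opposite_sex pair counts for the two groups.
#' @return An object of class \code{"weinberg"}: a list with \code{p_mz},
#'   \code{gamma}, \code{delta_same_sex} and the input counts. \code{p_mz}
#'   is clipped to \eqn{[0, 1]} with a warning when the opposite-sex group
#'   outnumbers the same-sex group (which would imply no MZ twins).
#' @examples
#' weinberg(22331, 11619)  # gamma ~ 0.74
#' @export
weinberg <- function(n_same_sex, n_opposite_sex) {
  stopifnot(n_same_sex >= 1, n_opposite_sex >= 0)
  p_mz <- (n_same_sex - n_opposite_sex) / n_same_sex
  if (p_mz < 0) {
    warning("more opposite-sex than same-sex pairs; ",
            "MZ proportion clipped to 0")
    p_mz <- 0
  }
  structure(list(p_mz = p_mz,
                 gamma = p_mz + 0.5 * (1 - p_mz),
                 delta_same_sex = p_mz + 0.25 * (1 - p_mz),
                 n_same_sex = n_same_sex,
                 n_opposite_sex = n_opposite_sex),
            class = "weinberg")
}

#' @export
print.weinberg <- function(x, digits = 4, ...) {
  cat("Weinberg-rule zygosity adjustment\n")
  cat("  same-sex pairs:    ", x$n_same_sex, "\n")
  cat("  opposite-sex pairs:", x$n_opposite_sex, "\n")
  cat("  MZ proportion among same-sex pairs:",
      format(x$p_mz, digits = digits), "\n")
  cat("  adjusted genetic correlation gamma:",
      format(x$gamma, digits = digits), "\n")
  cat("  adjusted dominance correlation:    ",
      format(x$delta_same_sex, digits = digits), "\n")
  invisible(x)
}

#' Group coefficients for the biometric expectation
#'
#' Per-group coefficients of the expected pair liability correlation:
#' genetic correlation \code{kappa}, dominance correlation \code{delta}
#' and shared-environment coefficient \code{c_coef}. The same-sex twin
#' group uses the Weinberg mixture coefficients; opposite-sex twins and
#' non-twin siblings use DZ coefficients (0.5, 0.25). The sibling
#' shared-environment coefficient defaults to 1 but can be lowered as a
#' sensitivity knob (siblings reared together may share less environment
#' than twins).
#'
#' @param adjustment a [weinberg()] object (or a single numeric gamma,
#'   from which the MZ proportion and dominance mixture are recovered).
#' @param sibling_c shared-environment coefficient for sibling pairs.
#' @return Data frame with one row per group label.
#' @export
group_coefficients <- function(adjustment, sibling_c = 1) {
  if (is.numeric(adjustment)) {
    stopifnot(length(adjustment) == 1, adjustment >= 0.5, adjustment <= 1)
    p_mz <- 2 * adjustment - 1
    adjustment <- list(gamma = adjustment,
                       delta_same_sex = p_mz + 0.25 * (1 - p_mz))
  }
  stopifnot(sibling_c >= 0, sibling_c <= 1)
  data.frame(
    group = GROUPS,
    kappa = c(adjustment$gamma, 0.5, 0.5),
    delta = c(adjustment$delta_same_sex, 0.25, 0.25),
    c_coef = c(1, 1, sibling_c),
    stringsAsFactors = FALSE
  )
}

#' Expected pair correlation under an ACE or ADE model
#'
#' \eqn{r = \kappa a^2 + c_{coef}\, c^2} (ACE) or
#' \eqn{r = \kappa a^2 + \delta d^2} (ADE) for one group.
#'
#' @param model \code{"ACE"} or \code{"ADE"}.
#' @param a2 additive-genetic variance fraction.
#' @param c2_or_d2 shared-environment (ACE) or dominance (ADE) fraction.
#' @param kappa,delta,c_coef group coefficients (see
#'   [group_coefficients()]).
#' @return Expected liability correlation.
#' @export
expected_pair_correlation <- function(model, a2, c2_or_d2, kappa,
                                      delta = 0.25, c_coef = 1) {
  model <- match.arg(model, c("ACE", "ADE"))
  if (model == "ACE") kappa * a2 + c_coef * c2_or_d2
  else kappa * a2 + delta * c2_or_d2
}

#' Closed-form method-of-moments variance decomposition
#'
#' Falconer-type solution of the biometric equations from two group
#' correlations, generalized to the Weinberg-mixture same-sex group. For
#' the ACE model,
#' \deqn{a^2 = (r_{ss} - r_{os}) / (\gamma - 0.5), \quad
#'       c^2 = r_{os} - 0.5 a^2, \quad e^2 = 1 - a^2 - c^2.}
#' For the ADE model the 2x2 linear system
#' \eqn{[\gamma, \delta_{ss}; 0.5, 0.25] (a^2, d^2)' = (r_{ss}, r_{os})'}
#' is solved. The raw solution is returned untruncated (components may
#' fall outside \eqn{[0,1]} with noisy inputs); it serves as an
#' independent cross-check of the maximum-likelihood fit.
#'
#' @param r_ss,r_os tetrachoric correlations for the same-sex and
#'   opposite-sex (or sibling) groups.
#' @param adjustment a [weinberg()] object or numeric gamma.
#' @param model \code{"ACE"} or \code{"ADE"}.
#' @return Named vector \code{c(a2, c2, e2)} or \code{c(a2, d2, e2)}.
#' @examples
#' mom_decompose(0.4218, 0.285, weinberg(22331, 11619))  # a2 ~ 0.57
#' @export
mom_decompose <- function(r_ss, r_os, adjustment, model = c("ACE", "ADE")) {
  model <- match.arg(model)
  co <- group_coefficients(adjustment)
  gamma <- co$kappa[co$group == "same_sex"]
  delta_ss <- co$delta[co$group == "same_sex"]
  if (model == "ACE") {
    if (abs(gamma - 0.5) < 1e-10)
      stop("gamma = 0.5: groups are not distinguishable, a2 unidentified")
    a2 <- (r_ss - r_os) / (gamma - 0.5)
    c2 <- r_os - 0.5 * a2
    c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2)
  } else {
    A <- matrix(c(gamma, delta_ss, 0.5, 0.25), nrow = 2, byrow = TRUE)
    if (abs(det(A)) < 1e-10) stop("singular coefficient system for ADE")
    sol <- solve(A, c(r_ss, r_os))
    c(a2 = sol[1], d2 = sol[2], e2 = 1 - sum(sol))
  }
}
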