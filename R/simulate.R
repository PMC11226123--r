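#' Liability threshold for a given prevalence
#'
#' Under the liability-threshold model a binary trait takes value 1 when a
#' latent standard-normal liability exceeds a threshold \eqn{\tau}. The
#' threshold is fixed by the population prevalence \eqn{K}:
#' \eqn{\tau = \Phi^{-1}(1 - K)}.
#'
#' @param K trait prevalence, strictly between 0 and 1.
#' @return The threshold in standard-normal units (decreasing in \code{K}).
#' @examples
#' liability_threshold(0.5)   # 0
#' liability_threshold(0.17)  # about 0.954
#' @export
liability_threshold <- function(K) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0) || any(K >= 1))
    stop("prevalence 'K' must lie strictly between 0 and 1")
  stats::qnorm(1 - K)
}

#' Expected liability correlation for a pair type
#'
#' Biometric expectation of the correlation between the latent liabilities
#' of two pair members: \eqn{r = \kappa a^2 + \delta d^2 + c^2}, where
#' \eqn{\kappa} is the genetic correlation of the pair type (1 for MZ
#' twins, 0.5 for DZ twins and full siblings), \eqn{\delta} the dominance
#' correlation (1 for MZ, 0.25 for DZ/siblings), and \eqn{a^2, d^2, c^2}
#' the standardized additive-genetic, dominance and shared-environment
#' variance fractions.
#'
#' @param a2,c2,d2 standardized variance fractions (\code{a2+c2+d2 <= 1}).
#' @param kappa genetic correlation coefficient of the pair type.
#' @param delta dominance correlation coefficient of the pair type.
#' @return Pair liability correlation in \eqn{[0, 1]}.
#' @examples
#' pair_liability_correlation(0.6, 0.1, kappa = 1)    # MZ: 0.7
#' pair_liability_correlation(0.6, 0.1, kappa = 0.5)  # DZ: 0.4
#' @export
pair_liability_correlation <- function(a2, c2 = 0, d2 = 0, kappa = 1,
                                       delta = 0.25) {
  check_components(a2, c2, d2)
  kappa * a2 + delta * d2 + c2
}

check_components <- function(a2, c2, d2 = 0) {
  if (any(c(a2, c2, d2) < 0) || a2 + c2 + d2 > 1 + 1e-12)
    stop("variance fractions must be non-negative with a2 + c2 + d2 <= 1")
  invisible(TRUE)
}

#' Simulate a twin/sibling registry with unknown zygosity
#'
#' Generates pair-level binary phenotype data with the statistical
#' structure assumed by the same-sex/opposite-sex twin design: latent
#' bivariate-normal liabilities with correlation
#' \eqn{\kappa a^2 + \delta d^2 + c^2} per true pair type, dichotomized at
#' the prevalence threshold. MZ pairs are hidden inside the same-sex group
#' (zygosity is never observed); each DZ pair is labelled opposite-sex with
#' probability \code{dz_opposite_sex_prob} and same-sex otherwise; sibling
#' pairs form their own group.
#'
#' Bivariate-normal draws use the Cholesky factor of the 2x2 correlation
#' matrix (\code{L2 = rho*L1 + sqrt(1-rho^2)*Z}) with R's default
#' Mersenne-Twister generator and inversion normals, so a fixed seed gives
#' reproducible data across platforms.
#'
#' MZ pairs, same-sex DZ pairs and sibling pairs receive a shared sex drawn
#' fair-coin (\code{"MM"}/\code{"FF"}); opposite-sex pairs are \code{"MF"}.
#'
#' @param n_mz,n_dz,n_sib numbers of MZ twin, DZ twin and (same-sex,
#'   non-twin) sibling pairs.
#' @param a2,c2,d2 generating standardized variance fractions
#'   (\code{a2 + c2 + d2 <= 1}; the remainder is unique environment).
#' @param prevalence trait prevalence \eqn{K} in (0, 1).
#' @param dz_opposite_sex_prob probability a DZ pair is opposite-sex
#'   (0.5 under independent sex assortment of DZ co-twins).
#' @param strata optional named list of per-stratum overrides; each element
#'   is a list with any of \code{a2}, \code{c2}, \code{d2},
#'   \code{prevalence}. Pair counts are split as evenly as possible across
#'   strata; a \code{stratum} column records membership.
#' @param seed optional integer seed.
#' @param debug if \code{TRUE}, emit hidden truth columns
#'   (\code{zygosity}, \code{liab_1}, \code{liab_2}) for oracle checks;
#'   estimation code never reads them.
#' @return A data frame with one row per pair: \code{pair_id},
#'   \code{group} (\code{same_sex}, \code{opposite_sex}, \code{sibling}),
#'   \code{pheno_1}, \code{pheno_2}, \code{sex_pair}, and \code{stratum}
#'   when strata are requested.
#' @examples
#' d <- simulate_pairs(n_mz = 100, n_dz = 200, a2 = 0.57, c2 = 0,
#'                     prevalence = 0.17, seed = 1)
#' table(d$group)
#' @export
simulate_pairs <- function(n_mz, n_dz, n_sib = 0, a2, c2 = 0, d2 = 0,
                           prevalence = 0.17, dz_opposite_sex_prob = 0.5,
                           strata = NULL, seed = NULL, debug = FALSE) {
  stopifnot(n_mz >= 0, n_dz >= 0, n_sib >= 0,
            dz_opposite_sex_prob >= 0, dz_opposite_sex_prob <= 1)
  check_components(a2, c2, d2)
  liability_threshold(prevalence)  # validates prevalence
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (n_mz + n_dz + n_sib == 0) {
    warning("zero pairs requested; returning empty data set")
    return(empty_pairs(strata, debug))
  }

  if (is.null(strata)) {
    out <- simulate_stratum(n_mz, n_dz, n_sib, a2, c2, d2, prevalence,
                            dz_opposite_sex_prob, debug)
  } else {
    if (is.null(names(strata)) || any(!nzchar(names(strata))))
      stop("'strata' must be a named list of override lists")
    ns <- length(strata)
    split_n <- function(n) {
      base <- rep(n %/% ns, ns)
      base + c(rep(1L, n %% ns), rep(0L, ns - n %% ns))
    }
    mzs <- split_n(n_mz); dzs <- split_n(n_dz); sbs <- split_n(n_sib)
    parts <- vector("list", ns)
    for (i in seq_len(ns)) {
      ov <- strata[[i]]
      bad <- setdiff(names(ov), c("a2", "c2", "d2", "prevalence"))
      if (length(bad))
        stop("unknown stratum override(s): ", paste(bad, collapse = ", "))
      g <- function(nm, def) if (!is.null(ov[[nm]])) ov[[nm]] else def
      part <- simulate_stratum(mzs[i], dzs[i], sbs[i],
                               g("a2", a2), g("c2", c2), g("d2", d2),
                               g("prevalence", prevalence),
                               dz_opposite_sex_prob, debug)
      part$stratum <- names(strata)[i]
      parts[[i]] <- part
    }
    out <- do.call(rbind, parts)
  }
  out$pair_id <- sprintf("pair_%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  front <- c("pair_id", "group", "pheno_1", "pheno_2", "sex_pair")
  out[, c(front, setdiff(names(out), front))]
}

simulate_stratum <- function(n_mz, n_dz, n_sib, a2, c2, d2, prevalence,
                             p_os, debug) {
  tau <- liability_threshold(prevalence)
  r_mz <- pair_liability_correlation(a2, c2, d2, kappa = 1, delta = 1)
  r_dz <- pair_liability_correlation(a2, c2, d2, kappa = 0.5, delta = 0.25)
  draw <- function(n, rho) {
    l1 <- stats::rnorm(n)
    l2 <- rho * l1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    cbind(l1, l2)
  }
  L <- rbind(draw(n_mz, r_mz), draw(n_dz, r_dz), draw(n_sib, r_dz))
  zyg <- rep(c("mz", "dz", "sib"), c(n_mz, n_dz, n_sib))
  grp <- character(length(zyg))
  grp[zyg == "mz"] <- "same_sex"
  grp[zyg == "dz"] <- ifelse(stats::runif(n_dz) < p_os,
                             "opposite_sex", "same_sex")
  grp[zyg == "sib"] <- "sibling"
  sex <- ifelse(grp == "opposite_sex", "MF",
                ifelse(stats::runif(length(grp)) < 0.5, "MM", "FF"))
  out <- data.frame(
    group = grp,
    pheno_1 = as.integer(L[, 1] > tau),
    pheno_2 = as.integer(L[, 2] > tau),
    sex_pair = sex,
    stringsAsFactors = FALSE
  )
  if (debug) {
    out$zygosity <- zyg
    out$liab_1 <- L[, 1]
    out$liab_2 <- L[, 2]
  }
  out
}

empty_pairs <- function(strata, debug) {
  out <- data.frame(pair_id = character(0), group = character(0),
                    pheno_1 = integer(0), pheno_2 = integer(0),
                    sex_pair = character(0), stringsAsFactors = FALSE)
  if (!is.null(strata)) out$stratum <- character(0)
  if (debug) {
    out$zygosity <- character(0)
    out$liab_1 <- numeric(0)
    out$liab_2 <- numeric(0)
  }
  out
}
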