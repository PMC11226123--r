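#' Stratified biometric fits
#'
#' Fits the ACE/ADE liability-threshold model separately within each level
#' of a stratifier (sex, birth-cohort band, education, income, ...). By
#' default the Weinberg adjustment \eqn{\gamma} is computed once from the
#' full data and shared across strata (the reproduction default for
#' analyses that compute a single global \eqn{\gamma});
#' \code{gamma = "stratum"} recomputes it within each stratum from that
#' stratum's own same-sex/opposite-sex pair counts, and a numeric value
#' fixes it directly.
#'
#' Strata that cannot support a fit (fewer than two groups with distinct
#' genetic correlation, or too few pairs) are flagged and skipped, not
#' silently dropped.
#'
#' @param records pair-level records (see [read_pairs()]).
#' @param stratify_by name of the stratifier column.
#' @param model,design,sibling_c,tau_by_group passed to [fit_biometric()].
#' @param gamma \code{"global"}, \code{"stratum"}, or a number in
#'   \eqn{[0.5, 1]}.
#' @param min_pairs minimum pairs per group within a stratum to attempt a
#'   fit.
#' @return An object of class \code{"stratified_fits"}: a named list of
#'   [fit_biometric()] results (or skip records of class
#'   \code{"skipped_stratum"}), with the stratifier and settings attached.
#' @export
fit_stratified <- function(records, stratify_by,
                           model = c("ACE", "ADE", "AE"),
                           design = c("twin", "twin_sibling"),
                           gamma = "global", sibling_c = 1,
                           tau_by_group = FALSE, min_pairs = 10) {
  model <- match.arg(model)
  design <- match.arg(design)
  records <- validate_pairs(records)
  if (!stratify_by %in% names(records))
    stop("stratifier ", dQuote(stratify_by), " not found; available: ",
         paste(setdiff(names(records), c("pair_id", "pheno_1", "pheno_2")),
               collapse = ", "))
  levels_ <- sort(unique(as.character(records[[stratify_by]])))
  if (length(levels_) < 2)
    stop("stratifier ", dQuote(stratify_by), " has a single level")

  gamma_arg <- gamma
  if (identical(gamma, "global")) {
    n_ss <- sum(records$group == "same_sex")
    n_os <- sum(records$group == "opposite_sex")
    if (n_ss >= 1 && n_os >= 1) gamma_arg <- weinberg(n_ss, n_os)
    else if (design == "twin_sibling")
      stop("global gamma needs same_sex and opposite_sex counts; ",
           "supply a numeric gamma for twin_sibling data without ",
           "opposite-sex pairs")
  }

  fits <- stats::setNames(vector("list", length(levels_)), levels_)
  for (lv in levels_) {
    sub <- records[records[[stratify_by]] == lv, , drop = FALSE]
    g <- if (identical(gamma_arg, "stratum")) NULL else gamma_arg
    res <- tryCatch({
      tb <- aggregate_pairs(sub)
      use <- switch(design, twin = c("same_sex", "opposite_sex"),
                    twin_sibling = c("same_sex", "sibling"))
      np <- tb$n_pairs[match(use, tb$group)]
      if (any(is.na(np)) || any(np < min_pairs))
        stop("insufficient data: needs >= ", min_pairs,
             " pairs in each of ", paste(use, collapse = " and "),
             if (design == "twin" && !"opposite_sex" %in% tb$group)
               " (no opposite-sex pairs in this stratum; use design = \"twin_sibling\" with sibling pairs)"
             else "")
      fit_biometric(tb, model = model, design = design, gamma = g,
                    sibling_c = sibling_c, tau_by_group = tau_by_group)
    }, error = function(e) {
      warning("stratum ", dQuote(lv), " skipped: ", conditionMessage(e),
              call. = FALSE)
      structure(list(stratum = lv, reason = conditionMessage(e)),
                class = "skipped_stratum")
    })
    fits[[lv]] <- res
  }
  if (all(vapply(fits, inherits, logical(1), "skipped_stratum")))
    stop("no stratum could be fitted (first reason: ",
         fits[[1]]$reason, ")")
  structure(fits, class = "stratified_fits", stratify_by = stratify_by,
            model = model, design = design)
}

#' @export
print.stratified_fits <- function(x, digits = 3, ...) {
  cat("Stratified ", attr(x, "model"), " fits by ",
      dQuote(attr(x, "stratify_by")), "\n\n", sep = "")
  for (lv in names(x)) {
    if (inherits(x[[lv]], "skipped_stratum")) {
      cat(lv, ": skipped (", x[[lv]]$reason, ")\n", sep = "")
    } else {
      f <- x[[lv]]
      cat(sprintf("%s: a2 = %.3f (SE %s), %s = %.3f, e2 = %.3f\n",
                  lv, f$a2,
                  ifelse(is.na(f$se_a2), "NA", sprintf("%.3f", f$se_a2)),
                  component_label(f$model), f$c2_or_d2, f$e2))
    }
  }
  invisible(x)
}

#' Two-sample Z test for a heritability difference
#'
#' Compares the estimated additive-genetic variance fraction between two
#' stratified fits with the usual two-sample statistic
#' \deqn{Z = (a^2_A - a^2_B) / \sqrt{SE_A^2 + SE_B^2},}
#' with a two-sided normal p-value.
#'
#' @param fit_a,fit_b two converged [fit_biometric()] results for the same
#'   phenotype and model.
#' @param labels optional character vector of length 2 naming the strata.
#' @return An object of class \code{"stratum_comparison"} (one-row data
#'   frame): estimates, SEs, \code{z}, \code{p}, \code{significant_05},
#'   and a reliability flag when either fit has a boundary component.
#' @examples
#' # identical fits compare to z = 0, p = 1
#' @export
compare_strata <- function(fit_a, fit_b, labels = c("A", "B")) {
  stopifnot(inherits(fit_a, "biometric_fit"),
            inherits(fit_b, "biometric_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged")
  if (fit_a$model != fit_b$model)
    stop("fits use different models (", fit_a$model, " vs ", fit_b$model, ")")
  se_a <- fit_a$se_a2; se_b <- fit_b$se_a2
  if (is.na(se_a) || is.na(se_b))
    stop("standard errors unavailable; cannot form Z statistic")
  if (se_a == 0 && se_b == 0)
    stop("degenerate comparison: both standard errors are zero")
  unreliable <- any(unlist(fit_a$boundary)) || any(unlist(fit_b$boundary))
  if (unreliable)
    warning("variance component at the zero boundary in at least one ",
            "stratum; Wald SEs and the Z test may be unreliable")
  z <- (fit_a$a2 - fit_b$a2) / sqrt(se_a^2 + se_b^2)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(stratum_a = labels[1], stratum_b = labels[2],
                    a2_a = fit_a$a2, a2_b = fit_b$a2,
                    se_a = se_a, se_b = se_b,
                    z = z, p = p, significant_05 = p < 0.05,
                    boundary_flag = unreliable,
                    stringsAsFactors = FALSE)
  class(out) <- c("stratum_comparison", "data.frame")
  out
}

#' All pairwise heritability comparisons among stratified fits
#'
#' @param fits a [fit_stratified()] result.
#' @return A data frame with one [compare_strata()] row per pair of
#'   fitted strata.
#' @export
compare_all_strata <- function(fits) {
  stopifnot(inherits(fits, "stratified_fits"))
  ok <- names(fits)[!vapply(fits, inherits, logical(1), "skipped_stratum")]
  if (length(ok) < 2) stop("need at least two fitted strata to compare")
  combs <- utils::combn(ok, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    compare_strata(fits[[combs[1, i]]], fits[[combs[2, i]]],
                   labels = combs[, i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
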