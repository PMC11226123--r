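#' Simulate a registry and write it to CSV
#'
#' Thin pipeline wrapper around [simulate_pairs()]: writes the pair-level
#' data as comma-separated text plus a plain-text provenance sidecar
#' (\code{<out>.provenance.txt}) recording the generating configuration,
#' seed and package version, so a data file can always be regenerated.
#'
#' @param out output CSV path.
#' @param ... arguments passed to [simulate_pairs()] (including
#'   \code{seed}).
#' @param config optional path to a YAML configuration file whose keys are
#'   [simulate_pairs()] arguments (including a nested \code{strata} map);
#'   explicit \code{...} arguments override the file. Requires the
#'   \pkg{yaml} package.
#' @return Invisibly, the simulated data frame.
#' @export
run_simulate <- function(out, ..., config = NULL) {
  args <- utils::modifyList(read_run_config(config), list(...))
  d <- do.call(simulate_pairs, args)
  utils::write.csv(d, out, row.names = FALSE, quote = FALSE)
  side <- paste0(out, ".provenance.txt")
  writeLines(c(
    paste0("package: twinliab ", as.character(utils::packageVersion("twinliab"))),
    paste0("written: simulate -> ", out),
    paste0("n_rows: ", nrow(d)),
    vapply(names(args), function(k)
      paste0(k, ": ", paste(deparse(args[[k]]), collapse = " ")),
      character(1))
  ), side)
  message("wrote ", nrow(d), " pairs to ", out)
  invisible(d)
}

read_run_config <- function(config) {
  if (is.null(config)) return(list())
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  cfg <- yaml::yaml.load_file(config)
  stopifnot(is.list(cfg))
  cfg
}

#' Full fitting pipeline: read, aggregate, correlate, decompose
#'
#' Runs the standard analysis on one pair-level data set: read and
#' validate, aggregate to concordance tables, estimate per-group
#' tetrachoric correlations, compute the Weinberg adjustment, and fit the
#' requested biometric model(s), optionally per stratum. Progress and
#' every estimate with its SE/CI is logged to the message stream (stderr);
#' the tidy results go to the returned data frame and, when \code{out} is
#' given, to CSV.
#'
#' @param input a pair-level CSV path or a data frame of pair records.
#' @param out optional path for the tidy results CSV.
#' @param models character vector among \code{"ACE"}, \code{"ADE"},
#'   \code{"AE"}.
#' @param design,sibling_c,tau_by_group passed to [fit_biometric()].
#' @param stratify_by optional stratifier column; when given, fits are per
#'   stratum via [fit_stratified()] and a pooled fit is added as stratum
#'   \code{"all"}.
#' @param gamma \code{"auto"} (alias \code{"global"}), \code{"stratum"},
#'   or a number in \eqn{[0.5, 1]}.
#' @param phenotype label recorded in the results.
#' @return A tidy data frame: phenotype, model, design, stratum, a2,
#'   se_a2, ci bounds, c2_or_d2 (with SE/CI), e2, tau, gamma, loglik,
#'   pairs per group, converged.
#' @export
run_fit <- function(input, out = NULL, models = "ACE",
                    design = "twin", stratify_by = NULL,
                    gamma = "auto", sibling_c = 1, tau_by_group = FALSE,
                    phenotype = "phenotype") {
  records <- if (is.data.frame(input)) validate_pairs(input)
             else read_pairs(input)
  message("stage read: ", nrow(records), " validated pairs")
  tables <- aggregate_pairs(records)
  message("stage aggregate: ", nrow(tables), " concordance table(s)")
  tet <- tetrachoric_by_group(tables)
  for (i in seq_len(nrow(tet)))
    message(sprintf("stage tetrachoric: %s rho = %.4f (SE %s)",
                    tet$group[i], tet$rho[i],
                    ifelse(is.na(tet$se_rho[i]), "NA",
                           sprintf("%.4f", tet$se_rho[i]))))
  if (identical(gamma, "auto")) gamma <- "global"

  rows <- list()
  for (model in models) {
    if (is.null(stratify_by)) {
      g <- if (identical(gamma, "global") || identical(gamma, "stratum"))
        NULL else gamma
      fit <- fit_biometric(records, model = model, design = design,
                           gamma = g, sibling_c = sibling_c,
                           tau_by_group = tau_by_group)
      rows[[length(rows) + 1]] <- tidy_fit(fit, phenotype, "all")
      log_fit(fit, "all")
    } else {
      fits <- fit_stratified(records, stratify_by, model = model,
                             design = design, gamma = gamma,
                             sibling_c = sibling_c,
                             tau_by_group = tau_by_group)
      for (lv in names(fits)) {
        if (inherits(fits[[lv]], "skipped_stratum")) next
        rows[[length(rows) + 1]] <- tidy_fit(fits[[lv]], phenotype, lv)
        log_fit(fits[[lv]], lv)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
    message("wrote results to ", out)
  }
  res
}

tidy_fit <- function(fit, phenotype, stratum) {
  data.frame(
    phenotype = phenotype, model = fit$model, design = fit$design,
    stratum = stratum,
    a2 = fit$a2, se_a2 = fit$se_a2,
    a2_ci_lo = fit$ci95_a2[1], a2_ci_hi = fit$ci95_a2[2],
    c2_or_d2 = fit$c2_or_d2, se_c2_or_d2 = fit$se_c2_or_d2,
    c2_ci_lo = fit$ci95_c2_or_d2[1], c2_ci_hi = fit$ci95_c2_or_d2[2],
    e2 = fit$e2, tau = fit$tau[1], gamma = fit$gamma,
    loglik = fit$loglik,
    n_ss = unname(fit$n_pairs_by_group["same_sex"]),
    n_other = sum(fit$n_pairs_by_group) -
      unname(fit$n_pairs_by_group["same_sex"]),
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
}

log_fit <- function(fit, stratum) {
  message(sprintf(
    "stage fit [%s | %s]: a2 = %.4f (SE %s, CI %s-%s), %s = %.4f, e2 = %.4f",
    fit$model, stratum, fit$a2,
    ifelse(is.na(fit$se_a2), "NA", sprintf("%.4f", fit$se_a2)),
    ifelse(is.na(fit$ci95_a2[1]), "NA", sprintf("%.3f", fit$ci95_a2[1])),
    ifelse(is.na(fit$ci95_a2[2]), "NA", sprintf("%.3f", fit$ci95_a2[2])),
    component_label(fit$model), fit$c2_or_d2, fit$e2))
}

#' Render fitted variance decompositions as a markdown report
#'
#' Formats the tidy output of [run_fit()] as a human-readable markdown
#' table of A / C (or D) / E shares per phenotype and stratum, grouped by
#' stratifier when stratified results are present.
#'
#' @param results a results data frame from [run_fit()] or a path to such
#'   a CSV.
#' @param out optional path for the markdown file.
#' @return The report as a character vector of lines, invisibly when
#'   \code{out} is given.
#' @export
run_report <- function(results, out = NULL) {
  if (is.character(results)) results <- utils::read.csv(results)
  need <- c("phenotype", "model", "stratum", "a2", "c2_or_d2", "e2")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    stop("malformed results: need columns ", paste(need, collapse = ", "))
  for (cc in c("a2_ci_lo", "a2_ci_hi"))
    if (is.null(results[[cc]])) results[[cc]] <- NA_real_
  lines <- c("# Variance decomposition of binary phenotypes", "")
  if (nrow(results) == 0) {
    lines <- c(lines, "No fits to report.")
  } else {
    fmt_ci <- function(lo, hi)
      ifelse(is.na(lo), "-", sprintf("[%.2f, %.2f]", lo, hi))
    for (strat in unique(results$stratum)) {
      sub <- results[results$stratum == strat, , drop = FALSE]
      lines <- c(lines, paste0("## Stratum: ", strat), "",
                 "| phenotype | model | A | 95% CI | C/D | E |",
                 "|---|---|---|---|---|---|")
      for (i in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf(
          "| %s | %s | %.2f | %s | %.2f | %.2f |",
          sub$phenotype[i], sub$model[i], sub$a2[i],
          fmt_ci(sub$a2_ci_lo[i], sub$a2_ci_hi[i]),
          sub$c2_or_d2[i], sub$e2[i]))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(out)) {
    writeLines(lines, out)
    message("wrote report to ", out)
    return(invisible(lines))
  }
  lines
}
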