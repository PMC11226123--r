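GROUPS <- c("same_sex", "opposite_sex", "sibling")

#' Read pair-level data from delimited text
#'
#' Reads one row per twin/sibling pair from a comma-separated file with a
#' header and validates it: the group label must be one of
#' \code{same_sex}, \code{opposite_sex}, \code{sibling}; phenotypes must be
#' 0/1. Rows with missing or non-binary phenotype values are dropped and
#' counted (complete-case handling per phenotype pair); an unknown group
#' label is a hard error naming the offending row.
#'
#' @param file path to a CSV file (or connection) with a header row.
#' @param schema optional named character vector mapping the canonical
#'   column names (\code{pair_id}, \code{group}, \code{pheno_1},
#'   \code{pheno_2}) to the names used in the file, e.g.
#'   \code{c(pheno_1 = "twin1_borrowed")}. Unmapped canonical names are
#'   looked up verbatim.
#' @return A validated data frame of pair records; the number of dropped
#'   rows is attached as attribute \code{"n_dropped"} and reported via
#'   \code{message()}.
#' @export
read_pairs <- function(file, schema = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no data rows in ", file)
  wanted <- c("pair_id", "group", "pheno_1", "pheno_2")
  cols <- stats::setNames(wanted, wanted)
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_cols <- setdiff(cols[c("group", "pheno_1", "pheno_2")], names(raw))
  if (length(missing_cols))
    stop("column(s) not found in file: ", paste(missing_cols, collapse = ", "))
  d <- raw
  for (canon in wanted) {
    if (cols[[canon]] %in% names(raw)) d[[canon]] <- raw[[cols[[canon]]]]
  }
  if (is.null(d$pair_id)) d$pair_id <- sprintf("row_%06d", seq_len(nrow(d)))
  validate_pairs(d)
}

#' @rdname read_pairs
#' @param records a data frame of pair records to validate in place.
#' @export
validate_pairs <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("group", "pheno_1", "pheno_2")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("pair records need column(s): ", paste(miss, collapse = ", "))
  bad_grp <- which(!(records$group %in% GROUPS))
  if (length(bad_grp))
    stop("unknown group label ", dQuote(records$group[bad_grp[1]]),
         " in row ", bad_grp[1],
         " (expected one of: ", paste(GROUPS, collapse = ", "), ")")
  p1 <- suppressWarnings(as.numeric(records$pheno_1))
  p2 <- suppressWarnings(as.numeric(records$pheno_2))
  ok <- !is.na(p1) & !is.na(p2) & p1 %in% c(0, 1) & p2 %in% c(0, 1)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("dropped ", n_dropped,
            " pair(s) with missing or non-binary phenotype values")
  out <- records[ok, , drop = FALSE]
  out$pheno_1 <- as.integer(p1[ok])
  out$pheno_2 <- as.integer(p2[ok])
  if (anyDuplicated(out$pair_id))
    stop("duplicated pair_id values in data")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Aggregate pair records into 2x2 concordance tables
#'
#' Builds one 2x2 table of pair outcomes per group (and per stratum level
#' when \code{stratify_by} is given). Because twin order is arbitrary in
#' registry-like data, each pair contributes half a count to
#' \eqn{(y_1, y_2)} and half to \eqn{(y_2, y_1)} (symmetrization), which
#' forces \code{n01 == n10} and a single shared threshold downstream;
#' fractional counts are retained (the multinomial likelihood accepts
#' non-integer weights).
#'
#' @param records validated pair records (see [read_pairs()]).
#' @param stratify_by optional name of a column in \code{records} whose
#'   levels define strata; the special value \code{NULL} pools everything
#'   into stratum \code{"all"}.
#' @return A data frame with columns \code{group}, \code{stratum},
#'   \code{n00}, \code{n01}, \code{n10}, \code{n11}, \code{n_pairs}.
#' @examples
#' d <- simulate_pairs(50, 100, a2 = 0.5, prevalence = 0.17, seed = 1)
#' aggregate_pairs(d)
#' @export
aggregate_pairs <- function(records, stratify_by = NULL) {
  records <- validate_pairs(records)
  if (is.null(stratify_by)) {
    records$..stratum <- "all"
  } else {
    if (!stratify_by %in% names(records))
      stop("stratifier ", dQuote(stratify_by), " not found; available: ",
           paste(setdiff(names(records),
                         c("pheno_1", "pheno_2", "pair_id")), collapse = ", "))
    records$..stratum <- as.character(records[[stratify_by]])
  }
  pieces <- split(records, list(records$group, records$..stratum),
                  drop = TRUE, sep = "\r")
  rows <- lapply(pieces, function(p) {
    c01 <- sum(p$pheno_1 == 0 & p$pheno_2 == 1)
    c10 <- sum(p$pheno_1 == 1 & p$pheno_2 == 0)
    data.frame(group = p$group[1], stratum = p$..stratum[1],
               n00 = sum(p$pheno_1 == 0 & p$pheno_2 == 0),
               n01 = (c01 + c10) / 2, n10 = (c01 + c10) / 2,
               n11 = sum(p$pheno_1 == 1 & p$pheno_2 == 1),
               n_pairs = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, match(out$group, GROUPS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# coerce a one-row concordance table (or a length-4 count vector in
# (n00, n01, n10, n11) order) to a named count vector
as_cell_counts <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(nrow(table) == 1, all(c("n00", "n01", "n10", "n11") %in%
                                      names(table)))
    n <- c(table$n00, table$n01, table$n10, table$n11)
  } else {
    stopifnot(is.numeric(table), length(table) == 4)
    n <- as.numeric(table)
  }
  if (any(n < 0)) stop("negative cell counts")
  if (sum(n) < 1) stop("concordance table must hold at least one pair")
  stats::setNames(n, c("n00", "n01", "n10", "n11"))
}
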