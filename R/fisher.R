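#' Build a disease-group x score-band contingency table for one gene
#'
#' Counts scored observations of `gene` per disease group and score band,
#' restricted to the requested bands. By default only the two positive
#' bands enter the table (the layout of a printed band-count summary);
#' set `bands` to all three to include negatives as a column. Requested
#' bands with no observations are kept as zero columns, and rows follow the
#' canonical disease-group order [DISEASE_GROUPS] (unknown labels follow,
#' in order of appearance).
#'
#' @param observations Data frame of IHC observations; scored on the fly
#'   with [score_ihc()] if no `band` column is present.
#' @param gene Gene name to tabulate.
#' @param bands Character vector of score bands to include as columns.
#' @return An integer matrix with disease groups as rows and bands as
#'   columns.
#' @export
build_contingency <- function(observations, gene,
                              bands = c("weak-moderate", "strong")) {
  if (!all(bands %in% SCORE_BANDS)) {
    abort(sprintf("Unknown band(s): %s", paste(setdiff(bands, SCORE_BANDS), collapse = ", ")))
  }
  obs <- as_tibble(observations)
  if (!"band" %in% colnames(obs)) obs <- score_ihc(obs)
  obs <- obs[obs$gene == gene, ]
  if (!nrow(obs)) {
    abort(sprintf("No observations for gene '%s'.", gene))
  }
  groups <- unique(as.character(obs$group))
  groups <- c(intersect(DISEASE_GROUPS, groups), setdiff(groups, DISEASE_GROUPS))
  tab <- table(factor(as.character(obs$group), levels = groups),
               factor(as.character(obs$band), levels = bands))
  out <- matrix(as.integer(tab), nrow = length(groups),
                dimnames = list(groups, bands))
  out
}

# Sum, over all tables with the observed margins, the probabilities of
# tables no more probable than the observed one. Tables are enumerated
# cell by cell with feasibility bounds; probabilities come from the
# multivariate hypergeometric mass
#   P(T) = prod(r_i!) prod(c_j!) / (N! prod(t_ij!)).
# Returns list(p, n_tables).
enumerate_fh <- function(counts, max_tables = 2e6) {
  row_m <- rowSums(counts)
  col_m <- colSums(counts)
  n_total <- sum(counts)
  r <- length(row_m)
  cc <- length(col_m)
  log_const <- sum(lfactorial(row_m)) + sum(lfactorial(col_m)) - lfactorial(n_total)
  lp_obs <- log_const - sum(lfactorial(counts))
  # point probabilities tied with the observed one (up to relative 1e-7) count
  cutoff <- lp_obs + log1p(1e-7)

  env <- new.env(parent = emptyenv())
  env$p <- 0
  env$total <- 0
  env$n_tables <- 0L

  recurse <- function(i, j, row_rem, col_rem, lf_acc) {
    # lf_acc accumulates sum(lfactorial(cells)) over filled cells
    if (i == r) {
      # last row forced by remaining column margins
      lp <- log_const - lf_acc - sum(lfactorial(col_rem))
      env$n_tables <- env$n_tables + 1L
      if (env$n_tables > max_tables) {
        abort(sprintf(
          "More than %g tables share these margins; complete enumeration is infeasible (a Monte-Carlo p-value would be needed).",
          max_tables))
      }
      env$total <- env$total + exp(lp)
      if (lp <= cutoff) env$p <- env$p + exp(lp)
      return(invisible())
    }
    if (j == cc) {
      # last cell of the row is forced by the row remainder
      if (row_rem > col_rem[cc]) return(invisible())
      col_rem2 <- col_rem
      col_rem2[cc] <- col_rem2[cc] - row_rem
      recurse(i + 1L, 1L, row_m[i + 1L], col_rem2, lf_acc + lfactorial(row_rem))
      return(invisible())
    }
    rest_cols <- sum(col_rem[(j + 1L):cc])
    lo <- max(0L, row_rem - rest_cols)
    hi <- min(row_rem, col_rem[j])
    if (lo > hi) return(invisible())
    for (x in lo:hi) {
      col_rem2 <- col_rem
      col_rem2[j] <- col_rem2[j] - x
      recurse(i, j + 1L, row_rem - x, col_rem2, lf_acc + lfactorial(x))
    }
  }
  recurse(1L, 1L, row_m[1L], col_m, 0)
  # probabilities over all margin-fixed tables sum to 1; normalising removes
  # the accumulated lgamma rounding (a single-table margin gives exactly 1)
  list(p = min(1, env$p / env$total), n_tables = env$n_tables)
}

#' Exact test of independence for an r x c contingency table
#'
#' Fisher's exact test in its Freeman-Halton r x c extension, computed by
#' complete enumeration: all tables with the observed row and column
#' margins are generated, and the two-sided p-value is the total
#' multivariate-hypergeometric probability of tables whose point
#' probability does not exceed the observed table's (with the standard
#' relative tie tolerance of 1e-7). Margins that admit a single table (for
#' example a zero column margin in a two-column table) give p = 1. Suitable
#' for the small biopsy-series tables this package targets (total N up to a
#' few dozen); enumeration beyond `max_tables` aborts rather than
#' approximating.
#'
#' @param counts Non-negative integer matrix with at least 2 rows and 2
#'   columns (e.g. from [build_contingency()]).
#' @param max_tables Abort threshold on the number of enumerated tables.
#' @return An object of class `fet_result` with fields `p_value`, `method`
#'   (`exact-2x2` or `enumeration-rxc`), `n_tables_enumerated` and `table`.
#' @examples
#' fisher_exact(matrix(c(17, 0, 3, 1, 5, 1), nrow = 3, byrow = TRUE))
#' @export
fisher_exact <- function(counts, max_tables = 2e6) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    abort("The contingency table must be at least 2 x 2.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  storage.mode(counts) <- "integer"
  res <- enumerate_fh(counts, max_tables = max_tables)
  structure(
    list(
      p_value = res$p,
      method = if (all(dim(counts) == 2L)) "exact-2x2" else "enumeration-rxc",
      n_tables_enumerated = res$n_tables,
      table = counts
    ),
    class = "fet_result"
  )
}

#' @export
print.fet_result <- function(x, ...) {
  cat(sprintf("Exact test (%s): p = %.6g  [%d table(s) enumerated]\n",
              x$method, x$p_value, x$n_tables_enumerated))
  print(x$table)
  invisible(x)
}

#' Tidy an exact-test result
#'
#' @param x A `fet_result`.
#' @param ... Unused.
#' @return One-row tibble with `p_value`, `method` and
#'   `n_tables_enumerated`.
#' @exportS3Method generics::tidy
tidy.fet_result <- function(x, ...) {
  tibble(p_value = x$p_value, method = x$method,
         n_tables_enumerated = x$n_tables_enumerated)
}
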