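#' Per-gene contingency tables and exact tests across disease stages
#'
#' The composed IHC pipeline: scores the observations, builds one disease
#' group x score band contingency table per gene, and runs the exact
#' Freeman-Halton test on each. By default the tested columns are the two
#' positive bands (weak-moderate, strong); `include_negative = TRUE` adds
#' negative samples as a third column. The summary renders each cell as a
#' `k/n` string where `n` is the total number of stained samples for that
#' gene and group — so with the default bands the two columns need not sum
#' to `n` (negatives are absent from both).
#'
#' @param observations IHC observation data frame (see [score_ihc()]).
#' @param genes Genes to analyse; defaults to all genes present, with the
#'   canonical panel members first.
#' @param include_negative Include the negative band as a test column?
#' @return An object of class `ihc_analysis` holding the scored
#'   observations, per-gene tables and `fet_result`s, and a report-layout
#'   `summary` tibble. See [tidy.ihc_analysis()] and
#'   [autoplot.ihc_analysis()].
#' @examples
#' cfg <- ihc_sim_config(genes = c("STRA8", "DMC1"), seed = 11)
#' fit <- run_ihc_analysis(simulate_ihc(cfg))
#' fit$summary
#' @export
run_ihc_analysis <- function(observations, genes = NULL, include_negative = FALSE) {
  scores <- score_ihc(observations)
  present <- unique(as.character(scores$gene))
  if (is.null(genes)) {
    genes <- c(intersect(MEICT_PANEL, present), setdiff(present, MEICT_PANEL))
  }
  missing <- setdiff(genes, present)
  if (length(missing)) {
    abort(sprintf("No observations for gene(s): %s", paste(missing, collapse = ", ")))
  }
  bands <- if (include_negative) SCORE_BANDS else c("weak-moderate", "strong")

  tables <- lapply(setNames(genes, genes), function(g) {
    build_contingency(scores, g, bands = bands)
  })
  tests <- lapply(tables, fisher_exact)

  summary <- dplyr::bind_rows(lapply(genes, function(g) {
    tab <- tables[[g]]
    n_tot <- table(factor(as.character(scores$group[scores$gene == g]),
                          levels = rownames(tab)))
    rows <- tibble(
      gene = g,
      group = rownames(tab),
      n = as.integer(n_tot[rownames(tab)])
    )
    for (b in colnames(tab)) {
      rows[[gsub("-", "_", b)]] <- sprintf("%d/%d", tab[, b], rows$n)
    }
    rows$p_value <- tests[[g]]$p_value
    rows
  }))

  structure(
    list(scores = scores, tables = tables, tests = tests, summary = summary,
         genes = genes, bands = bands, include_negative = include_negative),
    class = "ihc_analysis"
  )
}

#' @export
print.ihc_analysis <- function(x, ...) {
  cat(sprintf("IHC band analysis: %d gene(s), bands tested: %s\n\n",
              length(x$genes), paste(x$bands, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Tidy an IHC band analysis
#'
#' @param x An `ihc_analysis` object.
#' @param ... Unused.
#' @return Long tibble: one row per gene x disease group x band with the
#'   band `count`, the group total `n`, and the gene-level exact-test
#'   `p_value`.
#' @exportS3Method generics::tidy
tidy.ihc_analysis <- function(x, ...) {
  dplyr::bind_rows(lapply(x$genes, function(g) {
    tab <- x$tables[[g]]
    n_tot <- table(factor(as.character(x$scores$group[x$scores$gene == g]),
                          levels = rownames(tab)))
    tibble(
      gene = g,
      group = rep(rownames(tab), times = ncol(tab)),
      band = rep(colnames(tab), each = nrow(tab)),
      count = as.integer(tab),
      n = as.integer(n_tot[rep(rownames(tab), times = ncol(tab))]),
      p_value = x$tests[[g]]$p_value
    )
  }))
}

#' One-row summary of an IHC band analysis
#'
#' @param x An `ihc_analysis` object.
#' @param ... Unused.
#' @return One-row tibble with observation, gene and group counts and the
#'   banding mode.
#' @exportS3Method generics::glance
glance.ihc_analysis <- function(x, ...) {
  tibble(
    n_observations = nrow(x$scores),
    n_genes = length(x$genes),
    n_groups = length(unique(as.character(x$scores$group))),
    include_negative = x$include_negative
  )
}

#' Plot band composition by disease group for each gene
#'
#' Stacked proportional bars of score-band membership per disease group,
#' faceted by gene; the gene-level exact-test p-value is shown in the facet
#' strip.
#'
#' @param object An `ihc_analysis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ihc_analysis <- function(object, ...) {
  dat <- tidy(object)
  dat$facet <- sprintf("%s (p = %.2g)", dat$gene, dat$p_value)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$count,
                                    fill = .data$band)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~facet) +
    ggplot2::labs(x = NULL, y = "proportion of stained samples", fill = "band") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
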