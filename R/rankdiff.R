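#' Rank-fraction differential expression of a gene panel across cohorts
#'
#' The full pipeline behind a pooled-cohort panel comparison: converts each
#' cohort's TPM matrix to within-sample rank fractions, pools the panel
#' genes' fractions across cohorts with their case/control labels, and for
#' each panel gene computes the case/control mean-TPM ratio, the group mean
#' rank fractions, a pooled-null bootstrap p-value and its Bonferroni
#' adjustment (multiplicity = panel size; only panel genes are tested).
#'
#' Each gene's bootstrap runs under a child seed derived deterministically
#' from `(seed, gene position)`, so extending the panel never perturbs the
#' p-values of genes already in it.
#'
#' @param matrices TPM tibble or (named) list of them, one per cohort.
#' @param design Design table with columns `sample`, `cohort`, `group`.
#' @param panel Character vector of panel gene ids (order is report order).
#' @param n_bootstrap Bootstrap resamples per gene (default `1e5`, the
#'   smallest size that can resolve `p < 1e-5`).
#' @param seed Master integer seed.
#' @return An object of class `rankdiff`; see [tidy.rankdiff()],
#'   [glance.rankdiff()] and [autoplot.rankdiff()].
#' @examples
#' sim <- simulate_expression(expression_sim_config(
#'   n_genes = 200, group_sizes = c(6, 6),
#'   spike_genes = c(g00001 = 25), seed = 3))
#' fit <- run_rankdiff(sim$matrices, sim$design, panel = c("g00001", "g00002"),
#'                     n_bootstrap = 2000, seed = 3)
#' tidy(fit)
#' @export
run_rankdiff <- function(matrices, design, panel, n_bootstrap = 1e5, seed = 1L) {
  matrices <- as_matrix_list(matrices)
  check_design(design)
  fractions <- lapply(matrices, tpm_to_rank_fraction)
  pooled <- pool_cohorts(fractions, design, panel)
  ratios <- mean_tpm_ratio(matrices, design, panel)

  per_gene <- purrr::imap(panel, function(gene, i) {
    vals <- pooled[pooled$gene == gene, ]
    gseed <- child_seed(seed, i)
    p <- bootstrap_group_difference(
      vals$fraction[vals$group == "case"],
      vals$fraction[vals$group == "control"],
      n_bootstrap = n_bootstrap, seed = gseed
    )
    tibble(
      gene = gene,
      mean_fraction_control = mean(vals$fraction[vals$group == "control"]),
      mean_fraction_case = mean(vals$fraction[vals$group == "case"]),
      p_boot = p,
      seed = gseed
    )
  })
  results <- dplyr::bind_rows(per_gene)
  results <- dplyr::left_join(
    dplyr::select(ratios, "gene", "ratio_mean_tpm"), results, by = "gene")
  results$p_adj <- bonferroni(results$p_boot, m = length(panel))
  results$n_bootstrap <- as.integer(n_bootstrap)
  results <- dplyr::relocate(results, "p_adj", .after = "p_boot")

  structure(
    list(results = results, pooled = pooled, panel = panel,
         n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
         group_sizes = c(
           case = length(unique(design$sample[design$group == "case"])),
           control = length(unique(design$sample[design$group == "control"]))
         )),
    class = "rankdiff"
  )
}

#' @export
print.rankdiff <- function(x, ...) {
  cat(sprintf(
    "Rank-fraction differential expression: %d panel gene(s), %d case vs %d control samples\n",
    length(x$panel), x$group_sizes[["case"]], x$group_sizes[["control"]]))
  cat(sprintf("Bootstrap: B = %d (p floor %.3g), master seed %d\n\n",
              x$n_bootstrap, 1 / (x$n_bootstrap + 1), x$seed))
  print(x$results)
  invisible(x)
}

#' Tidy a rank-fraction differential expression fit
#'
#' One row per panel gene: the case/control mean-TPM ratio, group mean rank
#' fractions, bootstrap p-value, Bonferroni-adjusted p-value, and the
#' per-gene bootstrap settings.
#'
#' @param x A `rankdiff` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.rankdiff <- function(x, ...) {
  x$results
}

#' One-row summary of a rank-fraction differential expression fit
#'
#' @param x A `rankdiff` object.
#' @param ... Unused.
#' @return A one-row tibble: panel size, group sizes, bootstrap size, the
#'   attainable p-value floor `1/(B+1)`, and the master seed.
#' @exportS3Method generics::glance
glance.rankdiff <- function(x, ...) {
  tibble(
    n_panel = length(x$panel),
    n_case = x$group_sizes[["case"]],
    n_control = x$group_sizes[["control"]],
    n_bootstrap = x$n_bootstrap,
    p_floor = 1 / (x$n_bootstrap + 1),
    seed = x$seed
  )
}

#' Plot pooled rank fractions by group for each panel gene
#'
#' Boxplots of the pooled per-sample rank fractions (0 = most highly
#' expressed gene of a sample), split by case/control and faceted by gene,
#' with cohort shown by point shape. Lower fractions mean higher relative
#' expression.
#'
#' @param object A `rankdiff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rankdiff <- function(object, ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = .data$group, y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          ggplot2::aes(fill = .data$group), alpha = 0.4) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$cohort),
                         width = 0.15, height = 0, size = 1.5) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = NULL, y = "rank fraction (0 = top expressed gene)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}
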