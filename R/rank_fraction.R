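#' Convert a TPM matrix to within-sample rank fractions
#'
#' For gene `g` in sample `s`, the rank fraction is the proportion of the
#' *other* genes whose TPM strictly exceeds `g`'s:
#' \deqn{f(g, s) = \#\{g' \ne g : TPM(g', s) > TPM(g, s)\} / (n_{genes} - 1).}
#' The most highly expressed gene of a sample scores exactly 0 and tied
#' genes share a fraction; a sample's *unique* minimum scores exactly 1, so
#' on zero-inflated TPM data (where the bottom of the ranking is tied at 0)
#' all values fall in \[0, 1). The statistic depends only
#' on the within-sample ordering, so it is invariant under any strictly
#' monotone transform of a sample's TPM column — in particular under a
#' cohort-wide rescaling, which is what makes independently processed
#' cohorts poolable after conversion.
#'
#' Zero-TPM genes stay in the ranking universe: a gene with TPM 0 has
#' fraction equal to the proportion of genes with TPM > 0 in that sample.
#'
#' @param tpm Wide tibble/data frame: first column gene ids, remaining
#'   columns non-negative TPM values, one per sample. At least 2 genes.
#' @return Tibble of the same shape with TPMs replaced by rank fractions.
#' @examples
#' m <- tibble::tibble(gene_id = letters[1:5], s1 = c(10, 5, 0, 0, 0))
#' tpm_to_rank_fraction(m)$s1   # 0, 1/4, 2/4, 2/4, 2/4
#' @export
tpm_to_rank_fraction <- function(tpm) {
  parts <- unpack_expression(tpm)
  n <- length(parts$gene_ids)
  if (n < 2L) {
    abort("Rank fractions are undefined for a single-gene matrix (need >= 2 genes).")
  }
  if (any(parts$values < 0) || anyNA(parts$values)) {
    abort("TPM values must be non-negative and non-missing.")
  }
  # #{TPM > x} = n - max-rank(x); dividing by n - 1 puts the top gene at 0.
  frac <- apply(parts$values, 2L, function(x) {
    (n - rank(x, ties.method = "max")) / (n - 1)
  })
  pack_expression(parts$gene_ids, frac)
}

#' Pool per-cohort rank fractions for a gene panel
#'
#' Collects, for each panel gene, one rank fraction per sample across all
#' cohorts, tagged with its cohort and case/control group. Pooling happens
#' *after* per-cohort rank normalization; raw TPMs from differently scaled
#' cohorts are never mixed.
#'
#' @param fractions A rank-fraction tibble or (named) list of them, one per
#'   cohort, as produced by [tpm_to_rank_fraction()].
#' @param design Data frame with columns `sample`, `cohort`, `group`
#'   (`case`/`control`).
#' @param panel Character vector of panel gene ids; every cohort must
#'   contain every panel gene.
#' @return Long tibble with columns `gene`, `sample`, `cohort`, `group`,
#'   `fraction`.
#' @export
pool_cohorts <- function(fractions, design, panel) {
  fractions <- as_matrix_list(fractions)
  check_design(design)
  if (!is.character(panel) || !length(panel)) {
    abort("`panel` must be a non-empty character vector of gene ids.")
  }
  all_samples <- unlist(lapply(fractions, function(m) colnames(m)[-1L]))
  if (anyDuplicated(all_samples)) {
    abort(sprintf("Sample ids must be globally unique across cohorts; duplicated: %s",
                  paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")))
  }
  pooled <- purrr::imap(fractions, function(m, cohort) {
    parts <- unpack_expression(m, what = sprintf("cohort '%s'", cohort))
    missing <- setdiff(panel, parts$gene_ids)
    if (length(missing)) {
      abort(sprintf("Panel gene(s) %s missing from cohort '%s'.",
                    paste(missing, collapse = ", "), cohort))
    }
    sub <- parts$values[panel, , drop = FALSE]
    tibble(
      gene = rep(panel, times = ncol(sub)),
      sample = rep(colnames(sub), each = length(panel)),
      fraction = as.vector(sub)
    )
  })
  pooled <- dplyr::bind_rows(pooled)
  missing_design <- setdiff(unique(pooled$sample), design$sample)
  if (length(missing_design)) {
    abort(sprintf("Sample(s) missing from the design table: %s",
                  paste(missing_design, collapse = ", ")))
  }
  out <- dplyr::inner_join(pooled, as_tibble(design),
                           by = c(sample = "sample"))
  dplyr::select(out, "gene", "sample", "cohort", "group", "fraction")
}

#' Case/control ratio of mean TPM
#'
#' Computes, for each requested gene, the mean TPM over case samples divided
#' by the mean TPM over control samples, on raw TPMs pooled across cohorts.
#' When the control mean is 0 and the case mean positive the ratio is `Inf`
#' (rendered as the infinity sign in reports); when both means are 0 it is
#' undefined and returned as `NA`.
#'
#' @param matrices A TPM tibble or list of them (one per cohort).
#' @param design Design table (`sample`, `cohort`, `group`).
#' @param genes Character vector of gene ids to summarise.
#' @return Tibble with columns `gene`, `mean_tpm_case`, `mean_tpm_control`,
#'   `ratio_mean_tpm`.
#' @export
mean_tpm_ratio <- function(matrices, design, genes) {
  matrices <- as_matrix_list(matrices)
  check_design(design)
  parts <- lapply(matrices, unpack_expression)
  missing <- setdiff(genes, Reduce(union, lapply(parts, `[[`, "gene_ids")))
  if (length(missing)) {
    abort(sprintf("Gene(s) not present in any cohort: %s",
                  paste(missing, collapse = ", ")))
  }
  long <- dplyr::bind_rows(lapply(parts, function(p) {
    keep <- intersect(genes, p$gene_ids)
    sub <- p$values[keep, , drop = FALSE]
    tibble(gene = rep(keep, times = ncol(sub)),
           sample = rep(colnames(sub), each = length(keep)),
           tpm = as.vector(sub))
  }))
  long <- dplyr::inner_join(long, as_tibble(design), by = c(sample = "sample"))
  for (grp in c("case", "control")) {
    if (!any(long$group == grp)) abort(sprintf("The %s group is empty.", grp))
  }
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mean_tpm_case = mean(.data$tpm[.data$group == "case"]),
      mean_tpm_control = mean(.data$tpm[.data$group == "control"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_mean_tpm = dplyr::case_when(
        .data$mean_tpm_control > 0 ~ .data$mean_tpm_case / .data$mean_tpm_control,
        .data$mean_tpm_case > 0 ~ Inf,
        TRUE ~ NA_real_
      )
    )
  out[match(genes, out$gene), , drop = FALSE]
}
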