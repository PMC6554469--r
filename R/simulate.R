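#' Configuration for the synthetic expression-cohort generator
#'
#' Describes a multi-cohort bulk RNA-Seq experiment at the TPM level with a
#' hierarchical log-normal law: each gene draws a characteristic log-TPM
#' level from `Normal(baseline_log_mean, baseline_log_sd)` once, every
#' gene/sample value adds within-gene log-normal noise of spread
#' `noise_log_sd` (between-gene spread dominating within-gene noise, as in
#' real bulk RNA-Seq), each cohort is multiplied by its own global scale
#' factor (emulating two independently processed public cohorts), case
#' samples of spiked genes are multiplied by a fold change, and designated
#' testis-restricted genes are forced to exactly zero TPM in every control
#' sample (the STRA8-like pattern whose case/control mean ratio is
#' infinite).
#'
#' @param n_genes Number of genes per cohort matrix.
#' @param group_sizes Per-cohort group sizes: a matrix (or data frame) with
#'   one row per cohort and columns `case` and `control`, or a length-2
#'   vector `c(case, control)` recycled to every cohort.
#' @param cohort_scale_factors Positive global TPM scale per cohort; its
#'   length sets the number of cohorts. Names, if any, become cohort labels.
#' @param baseline_log_mean,baseline_log_sd Mean and standard deviation of
#'   the gene-level characteristic log-TPM levels.
#' @param noise_log_sd Within-gene, between-sample log-TPM noise spread.
#' @param spike_genes Named numeric vector: names are gene ids, values are
#'   multiplicative case-group fold changes (1 = null gene).
#' @param zero_in_control_genes Character vector of gene ids whose TPM is 0
#'   in every control sample of every cohort.
#' @param gene_ids Optional character vector of gene identifiers (length
#'   `n_genes`); defaults to `g00001 ...`.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `expression_sim_config`.
#' @seealso [simulate_expression()], [default_panel_sim_config()]
#' @export
expression_sim_config <- function(n_genes,
                                  group_sizes,
                                  cohort_scale_factors = 1,
                                  baseline_log_mean = 1,
                                  baseline_log_sd = 2,
                                  noise_log_sd = 0.5,
                                  spike_genes = numeric(),
                                  zero_in_control_genes = character(),
                                  gene_ids = NULL,
                                  seed = 1L) {
  # accept YAML/JSON-parsed configs, where vectors arrive as lists
  if (is.list(spike_genes)) spike_genes <- unlist(spike_genes)
  if (is.list(cohort_scale_factors)) cohort_scale_factors <- unlist(cohort_scale_factors)
  if (is.list(zero_in_control_genes)) zero_in_control_genes <- unlist(zero_in_control_genes)
  if (is.list(gene_ids)) gene_ids <- unlist(gene_ids)
  if (is.list(group_sizes) && !is.data.frame(group_sizes)) {
    group_sizes <- if (all(lengths(group_sizes) == 1L)) {
      unlist(group_sizes)
    } else {
      do.call(rbind, lapply(group_sizes, unlist))
    }
  }
  assert_scalar_number(n_genes, "n_genes", lower = 2)
  assert_scalar_number(baseline_log_sd, "baseline_log_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_log_sd, "noise_log_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(baseline_log_mean, "baseline_log_mean")
  assert_scalar_number(seed, "seed")
  if (!is.numeric(cohort_scale_factors) || !length(cohort_scale_factors) ||
      any(!is.finite(cohort_scale_factors)) || any(cohort_scale_factors <= 0)) {
    abort("`cohort_scale_factors` must be positive finite numbers, one per cohort.")
  }
  n_cohorts <- length(cohort_scale_factors)
  cohorts <- names(cohort_scale_factors)
  if (is.null(cohorts)) cohorts <- paste0("cohort", seq_len(n_cohorts))

  if (is.null(dim(group_sizes))) {
    if (length(group_sizes) != 2L) {
      abort("`group_sizes` must be c(case, control) or a cohort x group matrix.")
    }
    group_sizes <- matrix(rep(as.numeric(group_sizes), each = n_cohorts),
                          nrow = n_cohorts,
                          dimnames = list(cohorts, c("case", "control")))
  } else {
    group_sizes <- as.matrix(group_sizes)
    if (nrow(group_sizes) != n_cohorts || ncol(group_sizes) != 2L) {
      abort("`group_sizes` must have one row per cohort and columns case, control.")
    }
    colnames(group_sizes) <- c("case", "control")
    rownames(group_sizes) <- cohorts
  }
  if (any(group_sizes < 1) || any(group_sizes != round(group_sizes))) {
    abort("All group sizes must be positive integers.")
  }

  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    abort("`gene_ids` must be `n_genes` unique identifiers.")
  }
  if (length(spike_genes)) {
    if (is.null(names(spike_genes)) || any(!nzchar(names(spike_genes)))) {
      abort("`spike_genes` must be a named numeric vector (names = gene ids).")
    }
    missing <- setdiff(names(spike_genes), gene_ids)
    if (length(missing)) {
      abort(sprintf("spike_genes not in gene_ids: %s", paste(missing, collapse = ", ")))
    }
    if (any(spike_genes < 0) || any(!is.finite(spike_genes))) {
      abort("Fold changes must be finite and >= 0.")
    }
  }
  missing <- setdiff(zero_in_control_genes, gene_ids)
  if (length(missing)) {
    abort(sprintf("zero_in_control_genes not in gene_ids: %s",
                  paste(missing, collapse = ", ")))
  }

  structure(
    list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
         cohorts = cohorts, cohort_scale_factors = unname(cohort_scale_factors),
         baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
         noise_log_sd = noise_log_sd, spike_genes = spike_genes,
         zero_in_control_genes = as.character(zero_in_control_genes),
         gene_ids = as.character(gene_ids), seed = as.integer(seed)),
    class = "expression_sim_config"
  )
}

#' Default study-condition simulation config for the meiCT panel
#'
#' Two cohorts on different global TPM scales pooling to 25 case and 25
#' control samples, a 10^4-gene transcriptome, fold change 20 on all five
#' panel genes, and STRA8 additionally zero in every control sample.
#'
#' @param seed Integer seed.
#' @param fold_change Case-group fold change applied to every panel gene.
#' @param n_genes Transcriptome size.
#' @return An `expression_sim_config`.
#' @export
default_panel_sim_config <- function(seed = 1L, fold_change = 20, n_genes = 10000L) {
  gene_ids <- c(MEICT_PANEL, sprintf("g%05d", seq_len(n_genes - length(MEICT_PANEL))))
  expression_sim_config(
    n_genes = n_genes,
    group_sizes = rbind(c(13, 13), c(12, 12)),
    cohort_scale_factors = c(cohortA = 1, cohortB = 10),
    spike_genes = setNames(rep(fold_change, length(MEICT_PANEL)), MEICT_PANEL),
    zero_in_control_genes = "STRA8",
    gene_ids = gene_ids,
    seed = seed
  )
}

#' Simulate multi-cohort TPM expression matrices with known ground truth
#'
#' Draws one characteristic log-TPM level per gene from
#' `Normal(baseline_log_mean, baseline_log_sd)` (shared across cohorts, so
#' genes keep consistent relative expression), adds independent
#' `Normal(0, noise_log_sd)` log-noise per gene/sample, exponentiates,
#' multiplies each cohort by its global scale factor, multiplies
#' case-sample values of spiked genes by their fold change, and zeroes
#' control-sample values of the designated testis-restricted genes.
#'
#' @param config An [expression_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{matrices}{Named list (one per cohort) of wide tibbles: `gene_id`
#'       column then one column per sample.}
#'     \item{design}{Tibble with columns `sample`, `cohort`, `group`.}
#'     \item{truth}{Tibble with per-gene `fold_change`, `zero_in_control`
#'       and the logical `differential` flag.}
#'   }
#' @examples
#' sim <- simulate_expression(expression_sim_config(
#'   n_genes = 50, group_sizes = c(4, 4), seed = 7))
#' dim(sim$matrices[[1]])
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "expression_sim_config")) {
    abort("`config` must be built with expression_sim_config().")
  }
  with_seed(config$seed, {
    matrices <- vector("list", length(config$cohorts))
    names(matrices) <- config$cohorts
    design <- vector("list", length(config$cohorts))
    spike_idx <- match(names(config$spike_genes), config$gene_ids)
    zero_idx <- match(config$zero_in_control_genes, config$gene_ids)
    gene_mu <- stats::rnorm(config$n_genes, config$baseline_log_mean,
                            config$baseline_log_sd)

    for (k in seq_along(config$cohorts)) {
      n_case <- config$group_sizes[k, "case"]
      n_control <- config$group_sizes[k, "control"]
      n_samp <- n_case + n_control
      tpm <- exp(gene_mu + matrix(
        stats::rnorm(config$n_genes * n_samp, 0, config$noise_log_sd),
        nrow = config$n_genes
      )) * config$cohort_scale_factors[k]
      case_cols <- seq_len(n_case)
      control_cols <- n_case + seq_len(n_control)
      if (length(spike_idx)) {
        tpm[spike_idx, case_cols] <- tpm[spike_idx, case_cols, drop = FALSE] *
          unname(config$spike_genes)
      }
      if (length(zero_idx)) {
        tpm[zero_idx, control_cols] <- 0
      }
      samples <- c(sprintf("%s_case_%02d", config$cohorts[k], case_cols),
                   sprintf("%s_ctrl_%02d", config$cohorts[k], seq_len(n_control)))
      colnames(tpm) <- samples
      matrices[[k]] <- pack_expression(config$gene_ids, tpm)
      design[[k]] <- tibble(
        sample = samples,
        cohort = config$cohorts[k],
        group = rep(c("case", "control"), c(n_case, n_control))
      )
    }

    fold <- setNames(rep(1, config$n_genes), config$gene_ids)
    fold[names(config$spike_genes)] <- config$spike_genes
    zero <- config$gene_ids %in% config$zero_in_control_genes
    truth <- tibble(
      gene_id = config$gene_ids,
      fold_change = unname(fold),
      zero_in_control = zero,
      differential = unname(fold) != 1 | zero,
      seed = config$seed
    )
    list(matrices = matrices, design = dplyr::bind_rows(design), truth = truth)
  })
}

# ---- IHC simulation ---------------------------------------------------------

#' Outcome categories of a stained sample
#'
#' `Zero` (negative), or a percentage category I/II/III crossed with staining
#' intensity 1-3, written `III_2` etc.
#' @export
IHC_CATEGORIES <- c("Zero",
                    paste(rep(c("I", "II", "III"), each = 3), 1:3, sep = "_"))

#' Configuration for the synthetic IHC observation generator
#'
#' The unit of simulation is the scored category itself: for every
#' gene x disease group, observations are drawn from a multinomial over the
#' ten outcomes in [IHC_CATEGORIES] (no image synthesis).
#'
#' @param genes Character vector of gene names.
#' @param group_sizes Named integer vector of samples per disease group;
#'   default emulates a CTCL biopsy series (19 MF-I, 6 MF-II/III,
#'   7 aggressive).
#' @param category_probs Long tibble with columns `gene`, `group`,
#'   `category`, `prob`; each (gene, group) probability vector over
#'   [IHC_CATEGORIES] must sum to 1 within 1e-9. Alternatively `NULL` for
#'   uniform probabilities.
#' @param seed Integer seed.
#' @return A validated list of class `ihc_sim_config`.
#' @export
ihc_sim_config <- function(genes,
                           group_sizes = c("MF-I" = 19, "MF-II/III" = 6, "aggressive" = 7),
                           category_probs = NULL,
                           seed = 1L) {
  if (!is.character(genes) || !length(genes) || anyDuplicated(genes)) {
    abort("`genes` must be a non-empty character vector of unique names.")
  }
  if (is.null(names(group_sizes)) || any(group_sizes < 0) ||
      any(group_sizes != round(group_sizes))) {
    abort("`group_sizes` must be named non-negative integer counts.")
  }
  assert_scalar_number(seed, "seed")
  groups <- names(group_sizes)
  if (is.null(category_probs)) {
    category_probs <- tidyr::expand_grid(
      gene = genes, group = groups, category = IHC_CATEGORIES
    )
    category_probs$prob <- 1 / length(IHC_CATEGORIES)
  }
  needed <- c("gene", "group", "category", "prob")
  if (!is.data.frame(category_probs) || !all(needed %in% colnames(category_probs))) {
    abort("`category_probs` must have columns gene, group, category, prob.")
  }
  bad_cat <- setdiff(unique(category_probs$category), IHC_CATEGORIES)
  if (length(bad_cat)) {
    abort(sprintf("Unknown categories: %s", paste(bad_cat, collapse = ", ")))
  }
  if (any(category_probs$prob < 0)) abort("Probabilities must be >= 0.")
  sums <- dplyr::summarise(
    dplyr::group_by(category_probs, .data$gene, .data$group),
    total = sum(.data$prob), .groups = "drop"
  )
  full <- tidyr::expand_grid(gene = genes, group = groups)
  sums <- dplyr::left_join(full, sums, by = c("gene", "group"))
  if (any(is.na(sums$total)) || any(abs(sums$total - 1) > 1e-9)) {
    abort("Each (gene, group) probability vector must sum to 1 within 1e-9.")
  }
  structure(
    list(genes = genes, group_sizes = group_sizes,
         category_probs = as_tibble(category_probs), seed = as.integer(seed)),
    class = "ihc_sim_config"
  )
}

#' Simulate scored IHC observations
#'
#' For each gene and disease group, draws `group_sizes[group]` observations
#' from that cell's multinomial over [IHC_CATEGORIES] and expands each draw
#' into an observation record (`percent_category`, `intensity`; intensity is
#' `NA` for negative samples).
#'
#' @param config An [ihc_sim_config()].
#' @return Tibble with columns `sample`, `patient`, `group`, `gene`,
#'   `percent_category`, `intensity`.
#' @export
simulate_ihc <- function(config) {
  if (!inherits(config, "ihc_sim_config")) {
    abort("`config` must be built with ihc_sim_config().")
  }
  groups <- names(config$group_sizes)
  probs <- config$category_probs
  with_seed(config$seed, {
    rows <- list()
    for (group in groups) {
      n <- config$group_sizes[[group]]
      if (n == 0) next
      samples <- sprintf("%s_s%02d", gsub("[^A-Za-z0-9]+", "", group), seq_len(n))
      for (gene in config$genes) {
        p <- probs[probs$gene == gene & probs$group == group, ]
        p <- setNames(p$prob, p$category)[IHC_CATEGORIES]
        p[is.na(p)] <- 0
        draw <- sample(IHC_CATEGORIES, n, replace = TRUE, prob = p)
        pos <- draw != "Zero"
        inten <- rep(NA_integer_, n)
        inten[pos] <- as.integer(sub("^.*_", "", draw[pos]))
        rows[[length(rows) + 1L]] <- tibble(
          sample = samples,
          patient = samples,
          group = group,
          gene = gene,
          percent_category = sub("_[123]$", "", draw),
          intensity = inten
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
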