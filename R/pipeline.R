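#' Configuration for the full analysis pipeline
#'
#' Collects file paths and analysis settings for a reproducible run of the
#' rank-fraction differential expression stage and/or the IHC scoring and
#' exact-test stage. A stage runs only if its inputs are configured; all
#' randomness flows from the single master seed.
#'
#' @param matrix_paths Character vector of per-cohort TPM TSV paths (the
#'   rank-diff stage needs these plus `design_path` and `panel_path`).
#' @param design_path Path to the sample-design TSV.
#' @param panel_path Path to the gene-panel file.
#' @param ihc_path Path to the IHC observation CSV (enables the IHC stage).
#' @param out_dir Output directory (created if missing).
#' @param n_bootstrap Bootstrap resamples per panel gene; default `1e5`.
#' @param seed Master integer seed.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param include_negative_band Include negatives as a third IHC test
#'   column?
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_paths = NULL, design_path = NULL,
                            panel_path = NULL, ihc_path = NULL,
                            out_dir = ".", n_bootstrap = 1e5, seed = 1L,
                            alpha = 0.05, include_negative_band = FALSE) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) abort("`alpha` must lie strictly inside (0, 1).")
  assert_scalar_number(n_bootstrap, "n_bootstrap", lower = 1)
  assert_scalar_number(seed, "seed")
  rankdiff_on <- !is.null(matrix_paths)
  if (rankdiff_on && (is.null(design_path) || is.null(panel_path))) {
    abort("The rank-diff stage needs matrix_paths, design_path and panel_path.")
  }
  for (p in c(matrix_paths, design_path, panel_path, ihc_path)) {
    if (!file.exists(p)) {
      abort(sprintf("Configured input does not exist: %s", p),
            class = "meictools_config_error")
    }
  }
  if (!rankdiff_on && is.null(ihc_path)) {
    abort("Nothing to do: configure expression inputs, IHC inputs, or both.")
  }
  structure(
    list(matrix_paths = matrix_paths, design_path = design_path,
         panel_path = panel_path, ihc_path = ihc_path, out_dir = out_dir,
         n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
         alpha = alpha, include_negative_band = isTRUE(include_negative_band)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Field names match the arguments of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path), class = "meictools_config_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")),
          class = "meictools_config_error")
  }
  do.call(pipeline_config, raw)
}

#' Run the configured analysis stages end to end
#'
#' Reads the configured inputs, runs the rank-fraction differential
#' expression stage and/or the IHC stage, and writes the result TSVs and a
#' human-readable report into `out_dir`. Progress, group sizes, seeds and
#' skipped stages are logged via [message()]. A rerun with the same config
#' and seed produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `rankdiff` and/or
#'   `ihc_analysis` objects and the paths written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be built with pipeline_config() or read_pipeline_config().")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = character())
  message(sprintf("meictools %s | master seed %d | n_bootstrap %d | alpha %g",
                  as.character(packageVersion("meictools")),
                  config$seed, config$n_bootstrap, config$alpha))

  if (!is.null(config$matrix_paths)) {
    matrices <- lapply(config$matrix_paths, read_expression_tsv)
    names(matrices) <- sub("\\.[^.]*$", "", basename(config$matrix_paths))
    design <- read_design_tsv(config$design_path)
    panel <- read_panel_file(config$panel_path)
    message(sprintf("rank-diff stage: %d cohort(s), %d case / %d control samples, panel of %d",
                    length(matrices),
                    sum(design$group == "case"), sum(design$group == "control"),
                    length(panel)))
    fit <- run_rankdiff(matrices, design, panel,
                        n_bootstrap = config$n_bootstrap, seed = config$seed)
    p1 <- file.path(config$out_dir, "rankdiff_results.tsv")
    p2 <- file.path(config$out_dir, "rankdiff_report.txt")
    write_rankdiff_tsv(fit, p1)
    write_rankdiff_report(fit, p2)
    n_sig <- sum(fit$results$p_adj < config$alpha)
    message(sprintf("rank-diff stage: %d/%d panel gene(s) significant at alpha = %g after Bonferroni",
                    n_sig, length(panel), config$alpha))
    out$rankdiff <- fit
    out$paths <- c(out$paths, p1, p2)
  } else {
    message("rank-diff stage: skipped (no expression inputs configured)")
  }

  if (!is.null(config$ihc_path)) {
    obs <- read_ihc_csv(config$ihc_path)
    fit <- run_ihc_analysis(obs, include_negative = config$include_negative_band)
    message(sprintf("IHC stage: %d observation(s), %d gene(s), bands: %s",
                    nrow(fit$scores), length(fit$genes),
                    paste(fit$bands, collapse = ", ")))
    p1 <- file.path(config$out_dir, "ihc_scored.csv")
    p2 <- file.path(config$out_dir, "ihc_summary.tsv")
    write_ihc_csv(fit$scores, p1)
    write_ihc_summary_tsv(fit, p2)
    out$ihc <- fit
    out$paths <- c(out$paths, p1, p2)
  } else {
    message("IHC stage: skipped (no IHC inputs configured)")
  }
  invisible(out)
}
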