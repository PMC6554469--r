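# Readers and writers for the package's plain-text interchange formats:
# TSV for expression matrices, designs and result tables; CSV for IHC
# observations. All writers are deterministic (no timestamps) so identical
# inputs give identical bytes.

output_header <- function(...) {
  fields <- c(sprintf("meictools %s", as.character(packageVersion("meictools"))), ...)
  paste0("# ", paste(fields, collapse = "; "))
}

#' Read a TPM expression matrix from TSV
#'
#' Expects a header row (gene-id column then sample ids) and one row per
#' gene. Lines starting with `#` are ignored. Duplicate ids, missing,
#' negative or non-numeric values are parse errors naming the offending
#' gene row.
#'
#' @param path Path to a tab-separated file.
#' @return Wide tibble: `gene_id` column then one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path), class = "meictools_config_error")
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!nrow(x) || ncol(x) < 2L) {
    abort(sprintf("%s: expected a header plus gene rows with at least one sample column.", path))
  }
  colnames(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  vals <- x[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    abort(sprintf("%s: non-numeric TPM column(s): %s", path,
                  paste(colnames(vals)[non_num], collapse = ", ")))
  }
  bad <- which(apply(vals, 1L, function(r) anyNA(r) || any(r < 0)))
  if (length(bad)) {
    abort(sprintf("%s: negative or missing TPM at gene row %d (gene '%s').",
                  path, bad[1L], x$gene_id[bad[1L]]))
  }
  unpack_expression(x)  # validates duplicate ids
  as_tibble(x)
}

#' Write a TPM (or rank-fraction) matrix as TSV
#'
#' @param x Wide expression tibble (`gene_id` then sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  unpack_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample-design table (sample, cohort, group)
#'
#' @param path File path.
#' @return `read_design_tsv()`: a validated tibble.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path), class = "meictools_config_error")
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  check_design(x)
  as_tibble(x)
}

#' @param design Design tibble to write.
#' @rdname read_design_tsv
#' @export
write_design_tsv <- function(design, path) {
  check_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-panel file (one gene per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of gene ids in file order.
#' @export
read_panel_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path), class = "meictools_config_error")
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("%s: empty panel file.", path))
  if (anyDuplicated(lines)) abort(sprintf("%s: duplicate panel genes.", path))
  lines
}

#' Read or write IHC observations as CSV
#'
#' Columns: `sample`, `patient`, `group`, `gene`, `intensity`, and either
#' `percent_category` or `percent_positive`.
#'
#' @param path File path.
#' @return `read_ihc_csv()`: an observation tibble.
#' @export
read_ihc_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path), class = "meictools_config_error")
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  needed <- c("sample", "group", "gene", "intensity")
  if (!all(needed %in% colnames(x)) ||
      !any(c("percent_category", "percent_positive") %in% colnames(x))) {
    abort(sprintf("%s: expected columns %s plus percent_category or percent_positive.",
                  path, paste(needed, collapse = ", ")))
  }
  as_tibble(x)
}

#' @param observations Observation tibble to write (scored or not).
#' @rdname read_ihc_csv
#' @export
write_ihc_csv <- function(observations, path) {
  readr::write_csv(observations, path, progress = FALSE)
  invisible(path)
}

format_ratio <- function(r, infinity = "Inf") {
  dplyr::case_when(
    is.na(r) ~ "NA",
    is.infinite(r) ~ infinity,
    TRUE ~ formatC(r, format = "fg", digits = 6)
  )
}

#' Write rank-fraction differential expression results as TSV
#'
#' One row per panel gene in panel order, prefixed by a `#` header comment
#' recording the package version, master seed and bootstrap size. An
#' infinite mean-TPM ratio is rendered `Inf`, an undefined one `NA`.
#'
#' @param fit A `rankdiff` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankdiff_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "rankdiff"))
  res <- fit$results
  out <- tibble(
    gene = res$gene,
    ratio_mean_tpm_case_control = format_ratio(res$ratio_mean_tpm),
    mean_fraction_control = sprintf("%.6f", res$mean_fraction_control),
    mean_fraction_case = sprintf("%.6f", res$mean_fraction_case),
    p_boot = format(res$p_boot, digits = 6),
    p_adj = format(res$p_adj, digits = 6),
    n_bootstrap = res$n_bootstrap,
    seed = res$seed
  )
  header <- output_header(sprintf("seed=%d", fit$seed),
                          sprintf("n_bootstrap=%d", fit$n_bootstrap))
  readr::write_lines(header, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write a human-readable rank-fraction report
#'
#' A fixed-width text rendition of the results with the infinite ratio
#' printed as the infinity sign.
#'
#' @param fit A `rankdiff` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankdiff_report <- function(fit, path) {
  stopifnot(inherits(fit, "rankdiff"))
  res <- fit$results
  lines <- c(
    output_header(sprintf("seed=%d", fit$seed),
                  sprintf("n_bootstrap=%d", fit$n_bootstrap)),
    sprintf("Panel of %d gene(s); %d case vs %d control samples; p floor %.3g",
            length(fit$panel), fit$group_sizes[["case"]],
            fit$group_sizes[["control"]], 1 / (fit$n_bootstrap + 1)),
    "",
    sprintf("%-10s %12s %10s %10s %10s %10s",
            "gene", "ratio", "frac_ctrl", "frac_case", "p_boot", "p_adj"),
    sprintf("%-10s %12s %10.3f %10.3f %10.3g %10.3g",
            res$gene, format_ratio(res$ratio_mean_tpm, infinity = "∞"),
            res$mean_fraction_control, res$mean_fraction_case,
            res$p_boot, res$p_adj)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write the IHC band summary as TSV
#'
#' One row per gene x disease group in report layout: `k/n` strings per
#' band plus the gene-level exact-test p-value, prefixed by a `#` header
#' comment.
#'
#' @param analysis An `ihc_analysis` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ihc_summary_tsv <- function(analysis, path) {
  stopifnot(inherits(analysis, "ihc_analysis"))
  header <- output_header(sprintf("bands=%s", paste(analysis$bands, collapse = ",")))
  readr::write_lines(header, path)
  readr::write_tsv(analysis$summary, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
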