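# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
# Keeps seeds explicit function arguments rather than ambient state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for gene `index` under `master_seed`; stays in the
# 32-bit signed integer range so adding a panel gene never perturbs the seeds
# (hence the p-values) of the genes before it.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 1009 * as.numeric(index)) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range.", name, format(x)))
  }
  invisible(x)
}

# First column of a wide expression tibble is the gene identifier; the rest
# are samples. Returns list(gene_ids, sample_ids, values matrix).
unpack_expression <- function(x, what = "expression matrix") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("A %s needs a gene-id column plus at least one sample column.", what))
  }
  gene_ids <- as.character(x[[1L]])
  sample_ids <- colnames(x)[-1L]
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("Duplicate gene ids in %s: %s", what,
                  paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample ids in %s.", what))
  }
  values <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(values)) {
    abort(sprintf("Non-numeric values in %s.", what))
  }
  rownames(values) <- gene_ids
  list(gene_ids = gene_ids, sample_ids = sample_ids, values = values)
}

pack_expression <- function(gene_ids, values) {
  out <- as_tibble(as.data.frame(values, check.names = FALSE))
  dplyr::bind_cols(tibble(gene_id = gene_ids), out)
}

as_matrix_list <- function(matrices) {
  if (is.data.frame(matrices)) matrices <- list(matrices)
  if (!is.list(matrices) || !length(matrices)) {
    abort("`matrices` must be a data frame or a non-empty list of data frames.")
  }
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    names(matrices) <- paste0("cohort", seq_along(matrices))
  }
  matrices
}

check_design <- function(design) {
  needed <- c("sample", "cohort", "group")
  if (!is.data.frame(design) || !all(needed %in% colnames(design))) {
    abort("`design` must have columns sample, cohort and group.")
  }
  if (anyDuplicated(design$sample)) {
    abort("Duplicate sample ids in the design table.")
  }
  bad <- setdiff(unique(design$group), c("case", "control"))
  if (length(bad)) {
    abort(sprintf("Unknown group label(s): %s (expected case/control).",
                  paste(bad, collapse = ", ")))
  }
  invisible(design)
}
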