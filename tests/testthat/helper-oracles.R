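# Independent oracles and small fixture builders used across the suite.

# Quadratic exceedance-count oracle for rank fractions: for every gene,
# literally count the other genes with strictly greater TPM.
brute_force_rank_fraction <- function(values) {
  n <- nrow(values)
  out <- values
  for (s in seq_len(ncol(values))) {
    for (g in seq_len(n)) {
      out[g, s] <- sum(values[-g, s] > values[g, s]) / (n - 1)
    }
  }
  out
}

# Closed-form two-sided 2x2 Fisher p: sum hypergeometric point masses not
# exceeding the observed one (standard relative tie tolerance).
hyper_2x2_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(x_obs, m, n, k) * (1 + 1e-7)])
}

# Exact pooled-resampling p-value for tiny groups by full enumeration of all
# ordered with-replacement draws of pseudo-groups from the pool.
exact_boot_p <- function(case, control) {
  pool <- c(case, control)
  n1 <- length(case)
  n2 <- length(control)
  t_obs <- abs(mean(case) - mean(control))
  idx <- expand.grid(rep(list(seq_along(pool)), n1 + n2))
  t_star <- apply(idx, 1, function(ii) {
    abs(mean(pool[ii[seq_len(n1)]]) - mean(pool[ii[n1 + seq_len(n2)]]))
  })
  mean(t_star >= t_obs)
}

# Observation table realizing given per-group counts of negative /
# weak-moderate / strong samples for one gene (weak-moderate as I x 1,
# strong as III x 3).
make_band_obs <- function(gene, negative, weak_moderate, strong,
                          groups = c("MF-I", "MF-II/III", "aggressive")) {
  rows <- list()
  for (i in seq_along(groups)) {
    cats <- c(rep("Zero", negative[i]), rep("I", weak_moderate[i]),
              rep("III", strong[i]))
    inten <- c(rep(NA_integer_, negative[i]), rep(1L, weak_moderate[i]),
               rep(3L, strong[i]))
    n <- length(cats)
    if (!n) next
    rows[[i]] <- tibble::tibble(
      sample = sprintf("%s_%d_%02d", gene, i, seq_len(n)),
      patient = sprintf("p%d_%02d", i, seq_len(n)),
      group = groups[i],
      gene = gene,
      percent_category = cats,
      intensity = inten
    )
  }
  dplyr::bind_rows(rows)
}

# Small deterministic TPM matrix as a wide tibble.
make_tpm <- function(values, genes = sprintf("g%02d", seq_len(nrow(values))),
                     samples = sprintf("s%02d", seq_len(ncol(values)))) {
  colnames(values) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   tibble::as_tibble(as.data.frame(values)))
}
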