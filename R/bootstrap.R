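#' Pooled-null bootstrap test for a difference in group means
#'
#' Two-sided non-parametric test of equal means between two groups of rank
#' fractions. The observed statistic is `T = |mean(case) - mean(control)|`.
#' The null is generated by pooling both groups and drawing, with
#' replacement, pseudo-groups of the original sizes `n_bootstrap` times;
#' the p-value uses the add-one estimator
#' \deqn{p = (1 + \#\{T^* \ge T\}) / (n_{bootstrap} + 1),}
#' which never returns 0 and has resolution floor `1 / (n_bootstrap + 1)` —
#' claiming `p < 1e-5` therefore requires at least `1e5` resamples, the
#' default.
#'
#' @param values_case,values_control Numeric vectors, each of length >= 2.
#' @param n_bootstrap Number of bootstrap resamples (>= 1); default `1e5`.
#' @param seed Integer seed; results are reproducible and independent of
#'   the caller's RNG state.
#' @return The bootstrap p-value, a single number in (0, 1].
#' @examples
#' bootstrap_group_difference(c(0.1, 0.2), c(0.8, 0.9),
#'                            n_bootstrap = 1000, seed = 42)
#' @export
bootstrap_group_difference <- function(values_case, values_control,
                                       n_bootstrap = 1e5, seed = 1L) {
  if (length(values_case) < 2L || length(values_control) < 2L) {
    abort("Both groups need at least 2 values.")
  }
  if (anyNA(values_case) || anyNA(values_control)) {
    abort("Missing values are not allowed.")
  }
  assert_scalar_number(n_bootstrap, "n_bootstrap", lower = 1)
  n_bootstrap <- as.integer(round(n_bootstrap))
  n1 <- length(values_case)
  n2 <- length(values_control)
  pool <- c(values_case, values_control)
  n <- n1 + n2
  t_obs <- abs(mean(values_case) - mean(values_control))
  with_seed(seed, {
    exceed <- 0L
    done <- 0L
    chunk <- max(1L, min(n_bootstrap, as.integer(5e6 %/% n)))
    while (done < n_bootstrap) {
      b <- min(chunk, n_bootstrap - done)
      draws <- matrix(pool[sample.int(n, b * n, replace = TRUE)], nrow = b)
      m1 <- rowMeans(draws[, seq_len(n1), drop = FALSE])
      m2 <- rowMeans(draws[, n1 + seq_len(n2), drop = FALSE])
      exceed <- exceed + sum(abs(m1 - m2) >= t_obs)
      done <- done + b
    }
    (1 + exceed) / (n_bootstrap + 1)
  })
}

#' Bonferroni family-wise error correction
#'
#' Multiplies each p-value by the number of hypotheses `m` and caps at 1.
#' `m` defaults to the number of p-values supplied but may be larger (e.g.
#' when some tests of the family are reported elsewhere).
#'
#' @param p_values Numeric vector of p-values, each in (0, 1].
#' @param m Multiplicity, an integer >= `length(p_values)`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (!is.numeric(p_values) || !length(p_values) ||
      any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  assert_scalar_number(m, "m", lower = length(p_values))
  pmin(1, m * p_values)
}
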