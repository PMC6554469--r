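test_that("null configuration flags no gene as differential", {
  cfg <- expression_sim_config(n_genes = 50, group_sizes = c(3, 3), seed = 1)
  sim <- simulate_expression(cfg)
  expect_false(any(sim$truth$differential))
  expect_true(all(sim$truth$fold_change == 1))
})

test_that("zero-in-control genes have exactly zero TPM in every control sample", {
  cfg <- expression_sim_config(
    n_genes = 100, group_sizes = c(4, 5), cohort_scale_factors = c(1, 7),
    zero_in_control_genes = c("g00010", "g00020"), seed = 2)
  sim <- simulate_expression(cfg)
  controls <- sim$design$sample[sim$design$group == "control"]
  for (m in sim$matrices) {
    sub <- m[m$gene_id %in% c("g00010", "g00020"),
             intersect(colnames(m), controls)]
    expect_true(all(as.matrix(sub) == 0))
    cases <- m[m$gene_id == "g00010", setdiff(colnames(m)[-1], controls)]
    expect_true(all(as.matrix(cases) > 0))
  }
  expect_true(all(sim$truth$differential[sim$truth$gene_id %in% c("g00010", "g00020")]))
})

test_that("identical config and seed give identical simulations", {
  cfg <- expression_sim_config(n_genes = 80, group_sizes = c(3, 4),
                               cohort_scale_factors = c(1, 2),
                               spike_genes = c(g00005 = 8), seed = 99)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1, s2)

  icfg <- ihc_sim_config(genes = c("STRA8", "DMC1"), seed = 7)
  expect_identical(simulate_ihc(icfg), simulate_ihc(icfg))
})

test_that("null genes follow the configured hierarchical log-normal law", {
  cfg <- expression_sim_config(n_genes = 2000, group_sizes = c(5, 5),
                               baseline_log_mean = 1, baseline_log_sd = 2,
                               noise_log_sd = 0.5, seed = 5)
  sim <- simulate_expression(cfg)
  x <- log(as.matrix(sim$matrices[[1]][, -1]))   # 2e4 draws, 2000 genes
  # overall mean: gene effects average over n_genes, noise over all draws
  se_mean <- sqrt(2^2 / 2000 + 0.5^2 / length(x))
  expect_lt(abs(mean(x) - 1), 3 * se_mean)
  # spread of per-gene mean log-TPM: sqrt(sd_gene^2 + sd_noise^2 / n_samples)
  gm <- rowMeans(x)
  target <- sqrt(4 + 0.25 / 10)
  expect_lt(abs(sd(gm) - target), 3 * target / sqrt(2 * (2000 - 1)))
  # within-gene variance matches the noise spread
  wv <- mean(apply(x, 1, var))
  expect_lt(abs(wv - 0.25), 0.01)
})

test_that("spiked fold changes are recovered in empirical mean-TPM ratios", {
  spikes <- setNames(rep(20, 5), sprintf("g%05d", 1:5))
  cfg <- expression_sim_config(n_genes = 2000, group_sizes = c(25, 25),
                               spike_genes = spikes, seed = 1)
  sim <- simulate_expression(cfg)
  ratios <- mean_tpm_ratio(sim$matrices, sim$design, names(spikes))
  # law of large numbers at n = 25/25: within +/- 50% of the true fold 20
  expect_true(all(ratios$ratio_mean_tpm > 10 & ratios$ratio_mean_tpm < 30))

  # an independent re-draw with 10x the samples concentrates further
  cfg10 <- expression_sim_config(n_genes = 2000, group_sizes = c(250, 250),
                                 spike_genes = spikes, seed = 101)
  sim10 <- simulate_expression(cfg10)
  r10 <- mean_tpm_ratio(sim10$matrices, sim10$design, names(spikes))
  expect_true(all(abs(r10$ratio_mean_tpm - 20) <
                    abs(ratios$ratio_mean_tpm - 20) + 5))
})

test_that("invalid expression configs are rejected", {
  expect_error(expression_sim_config(n_genes = 1, group_sizes = c(3, 3)))
  expect_error(expression_sim_config(n_genes = 10, group_sizes = c(0, 3)))
  expect_error(expression_sim_config(n_genes = 10, group_sizes = c(3, 3),
                                     cohort_scale_factors = c(1, -2)))
  expect_error(expression_sim_config(n_genes = 10, group_sizes = c(3, 3),
                                     spike_genes = c(nope = 2)),
               "nope")
  expect_error(expression_sim_config(n_genes = 10, group_sizes = c(3, 3),
                                     zero_in_control_genes = "absent"),
               "absent")
})

test_that("degenerate IHC category probabilities are honoured exactly", {
  probs <- tidyr::expand_grid(gene = "STRA8",
                              group = c("MF-I", "aggressive"),
                              category = IHC_CATEGORIES)
  probs$prob <- as.numeric(probs$category == "Zero")
  cfg <- ihc_sim_config(genes = "STRA8",
                        group_sizes = c("MF-I" = 5, "aggressive" = 4),
                        category_probs = probs, seed = 3)
  obs <- simulate_ihc(cfg)
  expect_equal(nrow(obs), 9)
  expect_true(all(obs$percent_category == "Zero"))
  expect_true(all(is.na(obs$intensity)))

  probs$prob <- as.numeric(probs$category == "III_3")
  cfg <- ihc_sim_config(genes = "STRA8",
                        group_sizes = c("MF-I" = 5, "aggressive" = 4),
                        category_probs = probs, seed = 3)
  scored <- score_ihc(simulate_ihc(cfg))
  expect_true(all(scored$score == 9))
  expect_true(all(scored$band == "strong"))
})

test_that("IHC probability vectors must sum to one", {
  probs <- tidyr::expand_grid(gene = "STRA8", group = "MF-I",
                              category = IHC_CATEGORIES)
  probs$prob <- 0.2
  expect_error(ihc_sim_config(genes = "STRA8", group_sizes = c("MF-I" = 5),
                              category_probs = probs, seed = 1),
               "sum to 1")
})
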