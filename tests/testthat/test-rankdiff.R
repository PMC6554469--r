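test_that("a one-gene panel is its own family: p_adj equals p_boot", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 100, group_sizes = c(4, 4), seed = 8))
  fit <- run_rankdiff(sim$matrices, sim$design, panel = "g00001",
                      n_bootstrap = 500, seed = 8)
  expect_equal(fit$results$p_adj, fit$results$p_boot)
})

test_that("extending the panel leaves earlier genes' p-values untouched", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 150, group_sizes = c(5, 5), seed = 12))
  f2 <- run_rankdiff(sim$matrices, sim$design, panel = c("g00001", "g00002"),
                     n_bootstrap = 400, seed = 12)
  f3 <- run_rankdiff(sim$matrices, sim$design,
                     panel = c("g00001", "g00002", "g00003"),
                     n_bootstrap = 400, seed = 12)
  expect_equal(f2$results$p_boot, f3$results$p_boot[1:2])
})

test_that("strong spikes on the panel are all detected after correction", {
  spikes <- setNames(rep(20, 5), c("STRA8", "STAG3", "SGO2", "SYCP3", "DMC1"))
  cfg <- expression_sim_config(
    n_genes = 2000, group_sizes = rbind(c(13, 13), c(12, 12)),
    cohort_scale_factors = c(1, 10), spike_genes = spikes,
    zero_in_control_genes = "STRA8",
    gene_ids = c(names(spikes), sprintf("g%05d", 1:1995)), seed = 4)
  sim <- simulate_expression(cfg)
  fit <- run_rankdiff(sim$matrices, sim$design, panel = names(spikes),
                      n_bootstrap = 999, seed = 4)
  expect_true(all(fit$results$p_adj < 0.05))
  # spiked genes sit higher in the case ranking (smaller fraction)
  expect_true(all(fit$results$mean_fraction_case <
                    fit$results$mean_fraction_control))
  expect_equal(fit$results$ratio_mean_tpm[1], Inf)
})

test_that("family-wise error is controlled on null panels", {
  null_free <- vapply(1:200, function(i) {
    sim <- simulate_expression(expression_sim_config(
      n_genes = 60, group_sizes = c(5, 5), seed = 5000 + i))
    fit <- run_rankdiff(sim$matrices, sim$design,
                        panel = sprintf("g%05d", 1:5),
                        n_bootstrap = 199, seed = 5000 + i)
    all(fit$results$p_adj >= 0.05)
  }, logical(1))
  # nominal FWER 0.05 => >= 95% clean runs, allow the binomial 99% band
  expect_gte(mean(null_free), 0.92)
})

test_that("rankdiff results carry every report column and tidy/glance work", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 100, group_sizes = c(4, 4), seed = 3))
  fit <- run_rankdiff(sim$matrices, sim$design, panel = c("g00001", "g00002"),
                      n_bootstrap = 300, seed = 3)
  td <- tidy(fit)
  expect_named(td, c("gene", "ratio_mean_tpm", "mean_fraction_control",
                     "mean_fraction_case", "p_boot", "p_adj", "seed",
                     "n_bootstrap"))
  expect_true(all(td$p_boot >= 1 / 301 & td$p_boot <= 1))
  gl <- glance(fit)
  expect_equal(gl$p_floor, 1 / 301)
  expect_equal(gl$n_case, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})
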