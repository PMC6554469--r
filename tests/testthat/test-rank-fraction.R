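test_that("rank fractions follow the strict-exceedance definition", {
  m <- make_tpm(matrix(c(10, 5, 0, 0, 0), ncol = 1))
  expect_equal(tpm_to_rank_fraction(m)[[2]], c(0, 1/4, 2/4, 2/4, 2/4))

  # all genes tied: nothing strictly above anything
  m <- make_tpm(matrix(rep(3, 8), ncol = 2))
  fr <- tpm_to_rank_fraction(m)
  expect_true(all(as.matrix(fr[, -1]) == 0))
})

test_that("rank fractions match the brute-force exceedance oracle", {
  set.seed(42)
  vals <- matrix(rlnorm(50 * 4), nrow = 50)
  vals[sample(length(vals), 40)] <- 0   # heavy ties at zero
  fr <- tpm_to_rank_fraction(make_tpm(vals))
  expect_equal(as.matrix(fr[, -1]), brute_force_rank_fraction(vals),
               ignore_attr = TRUE)
})

test_that("rank fractions are invariant under per-sample monotone rescaling", {
  set.seed(7)
  vals <- matrix(rlnorm(60 * 5), nrow = 60)
  fr <- tpm_to_rank_fraction(make_tpm(vals))
  scaled <- sweep(vals, 2, c(0.01, 1, 10, 250, 1e4), `*`)
  fr2 <- tpm_to_rank_fraction(make_tpm(scaled))
  expect_equal(fr, fr2)
})

test_that("single-gene matrices are rejected", {
  expect_error(tpm_to_rank_fraction(make_tpm(matrix(5, 1, 2))), "single-gene")
  expect_error(tpm_to_rank_fraction(make_tpm(matrix(-1, 3, 1))), "non-negative")
})

test_that("pooling conserves samples and happens after per-cohort ranking", {
  set.seed(11)
  a_vals <- matrix(rlnorm(40 * 3), nrow = 40,
                   dimnames = list(NULL, paste0("a", 1:3)))
  b_vals <- a_vals[, 1:2] * 10   # cohort B = rescaled A subset
  a <- make_tpm(a_vals, samples = paste0("a", 1:3))
  b <- make_tpm(b_vals, samples = paste0("b", 1:2))
  design <- tibble::tibble(
    sample = c(paste0("a", 1:3), paste0("b", 1:2)),
    cohort = rep(c("A", "B"), c(3, 2)),
    group = c("case", "case", "control", "case", "case")
  )
  pooled <- pool_cohorts(list(A = tpm_to_rank_fraction(a),
                              B = tpm_to_rank_fraction(b)),
                         design, panel = c("g01", "g02"))
  expect_equal(nrow(pooled), 2 * 5)
  # scale invariance: the B samples reproduce the fractions of a1, a2
  for (g in c("g01", "g02")) {
    pa <- pooled$fraction[pooled$gene == g & pooled$sample %in% c("a1", "a2")]
    pb <- pooled$fraction[pooled$gene == g & pooled$cohort == "B"]
    expect_equal(sort(pa), sort(pb))
  }
})

test_that("pooling errors name the missing gene and cohort", {
  m <- tpm_to_rank_fraction(make_tpm(matrix(rlnorm(20), nrow = 10)))
  design <- tibble::tibble(sample = c("s01", "s02"), cohort = "A",
                           group = c("case", "control"))
  expect_error(pool_cohorts(list(A = m), design, panel = "missing_gene"),
               "missing_gene.*cohort 'A'")
  # globally duplicated sample ids across cohorts
  expect_error(pool_cohorts(list(A = m, B = m), design, panel = "g01"),
               "unique")
})

test_that("mean TPM ratio handles finite, infinite and undefined cases", {
  vals <- rbind(c(40, 50, 60, 2, 3),
                c(5, 5, 5, 5, 5),
                c(3, 4, 5, 0, 0),
                c(0, 0, 0, 0, 0))
  m <- make_tpm(vals)
  design <- tibble::tibble(sample = sprintf("s%02d", 1:5), cohort = "A",
                           group = rep(c("case", "control"), c(3, 2)))
  r <- mean_tpm_ratio(m, design, c("g01", "g02", "g03", "g04"))
  expect_equal(r$ratio_mean_tpm, c(20, 1, Inf, NA))
  expect_error(mean_tpm_ratio(m, design, "nope"), "nope")
  design$group <- "case"
  expect_error(mean_tpm_ratio(m, design, "g01"), "control group is empty")
})
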