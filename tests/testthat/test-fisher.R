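test_that("contingency tables reproduce known band counts", {
  # a biopsy series with band counts 17/3/5 weak-moderate, 0/1/1 strong
  obs <- make_band_obs("STRA8", negative = c(1, 2, 1),
                       weak_moderate = c(17, 3, 5), strong = c(0, 1, 1))
  tab <- build_contingency(obs, "STRA8")
  expect_equal(unname(tab), matrix(c(17, 3, 5, 0, 1, 1), nrow = 3))
  expect_equal(rownames(tab), c("MF-I", "MF-II/III", "aggressive"))
  # empty band columns are retained, not dropped
  expect_equal(colnames(tab), c("weak-moderate", "strong"))
  # conservation over the included bands
  expect_equal(sum(tab), sum(c(17, 3, 5, 0, 1, 1)))
  # negatives appear when requested as a third column
  tab3 <- build_contingency(obs, "STRA8", bands = SCORE_BANDS)
  expect_equal(unname(tab3[, "negative"]), c(1, 2, 1))
  expect_equal(sum(tab3), nrow(obs))
  expect_error(build_contingency(obs, "SYCP3"), "SYCP3")
})

test_that("enumeration matches the closed-form 2x2 hypergeometric p", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  set.seed(99)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    res <- fisher_exact(tab)
    expect_equal(res$p_value, hyper_2x2_p(tab), tolerance = 1e-12)
    expect_equal(res$method, "exact-2x2")
  }
})

test_that("the r x c enumeration agrees with an independent implementation", {
  tab <- matrix(c(17, 0, 3, 1, 5, 1), nrow = 3, byrow = TRUE)
  res <- fisher_exact(tab)
  expect_equal(res$method, "enumeration-rxc")
  expect_equal(res$p_value, 0.1282051, tolerance = 1e-6)
  expect_equal(res$p_value, stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  set.seed(123)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 4), nrow = 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("margins admitting a single table give p = 1", {
  res <- fisher_exact(matrix(c(16, 0, 5, 0, 6, 0), nrow = 3, byrow = TRUE))
  expect_equal(res$p_value, 1)
  expect_equal(res$n_tables_enumerated, 1L)
})

test_that("the exact p is invariant under row and column permutations", {
  set.seed(31)
  tab <- matrix(rpois(6, 6), nrow = 3)
  p <- fisher_exact(tab)$p_value
  expect_equal(fisher_exact(tab[c(3, 1, 2), ])$p_value, p, tolerance = 1e-12)
  expect_equal(fisher_exact(tab[, c(2, 1)])$p_value, p, tolerance = 1e-12)
})

test_that("malformed tables and infeasible enumerations are rejected", {
  expect_error(fisher_exact(matrix(1:3, ncol = 1)), "2 x 2")
  expect_error(fisher_exact(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(1.5, 1, 2, 3), 2)), "non-negative")
  big <- matrix(200L, 4, 4)
  expect_error(fisher_exact(big, max_tables = 1000), "Monte-Carlo")
})
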