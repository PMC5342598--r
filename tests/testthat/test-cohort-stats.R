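test_that("incidence summaries reproduce printed cohort percentages", {
  lab <- c(rep("NKP44_1_DOMINANT", 21), rep("NEGATIVE", 2))
  inc <- incidence(lab, "spontaneous")
  expect_equal(inc$n_positive, 21)
  expect_equal(round(inc$percent_positive, 1), 91.3)
  expect_equal(incidence(rep("NKP30_AB", 7), "elective")$percent_positive, 100)
  expect_equal(incidence(rep("NEGATIVE", 5), "x")$percent_positive, 0)
  expect_error(incidence(character(), "empty"), "empty group")
})

test_that("profile distributions use positive cases as denominator", {
  lab <- c(rep("NKP44_1_DOMINANT", 6), "NKP44_2_3", rep("NEGATIVE", 3))
  d <- profile_distribution(lab, "elective")
  expect_equal(d$count[d$label == "NKP44_1_DOMINANT"], 6)
  expect_equal(round(d$percent[d$label == "NKP44_1_DOMINANT"], 2), 85.71)
  expect_equal(sum(d$percent), 100)
  # percents reconstruct their counts
  n_pos <- sum(d$count)
  expect_equal(round(d$percent * n_pos / 100), d$count)
  d30 <- profile_distribution(c(rep("NKP30_AB", 8), rep("NKP30_C", 7)), "term")
  expect_equal(round(d30$percent, 2), c(53.33, 46.67))
  expect_equal(profile_distribution(c("NKP30_AB", "NKP30_AB",
                                      "NKP30_C", "NKP30_C"), "pe")$percent,
               c(50, 50))
  expect_error(profile_distribution(rep("NEGATIVE", 3), "allneg"),
               "no positive")
  expect_error(profile_distribution(character(), "none"), "empty group")
})

test_that("Fisher exact matches hand-enumerated examples", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # margins (7,21)x(11,17): p(6)+p(7) = (7854+330)/1184040
  expect_equal(fisher_exact_two_sided(matrix(c(6, 1, 5, 16), 2,
                                             byrow = TRUE))$p_value,
               8184 / 1184040, tolerance = 1e-12)
  # only the two extreme tables reach the observed point probability
  expect_equal(fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2,
                                             byrow = TRUE))$p_value,
               2 * choose(10, 10) * choose(10, 0) / choose(20, 10),
               tolerance = 1e-12)
  expect_warning(res <- fisher_exact_two_sided(c(0, 0, 3, 4)), "zero margin")
  expect_equal(res$p_value, 1)
})

test_that("Fisher exact agrees with brute-force and library oracles", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_two_sided(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-9)
    if (i %% 50 == 0) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_two_sided(tab)$p_value
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1])$p_value, p,
                 tolerance = 1e-12)
    expect_gte(p, exp(lchoose(sum(tab[1, ]), tab[1, 1]) +
                      lchoose(sum(tab[2, ]), tab[2, 1]) -
                      lchoose(sum(tab), sum(tab[, 1]))))
  }
})

test_that("paired t-test matches the df=2 closed form and the library", {
  res <- paired_t_two_tail(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, sqrt(12), tolerance = 1e-9)
  # closed form for df = 2: p = 1 - t/sqrt(t^2 + 2)
  expect_equal(res$p_value, 1 - sqrt(12) / sqrt(12 + 2), tolerance = 1e-9)
  expect_equal(round(res$p_value, 4), 0.0742)
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(paired_t_two_tail(x, y)$p_value,
               stats::t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-12)
  # antisymmetry
  expect_equal(paired_t_two_tail(y, x)$statistic,
               -paired_t_two_tail(x, y)$statistic)
  expect_equal(paired_t_two_tail(y, x)$p_value,
               paired_t_two_tail(x, y)$p_value)
  # zero-mean differences give p = 1; zero variance errors
  expect_equal(paired_t_two_tail(c(2, -2, 2, -2), rep(0, 4))$p_value, 1)
  expect_error(paired_t_two_tail(c(1, 1, 1), c(0, 0, 0)), "zero variance")
})

test_that("group comparison builds the 2x2 and runs Fisher", {
  res <- compare_groups(c(6, 1), c(5, 16))
  expect_equal(res$table, rbind(A = c(6, 1), B = c(5, 16)))
  expect_lt(res$test$p_value, 0.05)
  expect_equal(compare_groups(c(3, 7), c(3, 7))$test$p_value, 1)
  expect_error(compare_groups(c(0, 0), c(1, 2)), "at least one")
})
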