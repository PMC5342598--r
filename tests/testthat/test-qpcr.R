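test_that("relative expression follows the 2^-dCt closed form", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(25, 20), 0.03125)
  expect_equal(relative_expression(18, 21), 8)
  # identity for any Ct, and monotonicity in both arguments
  for (ct in c(5, 18.3, 33, 40)) {
    expect_equal(relative_expression(ct, ct), 1)
  }
  expect_true(relative_expression(26, 20) < relative_expression(25, 20))
  expect_true(relative_expression(25, 21) > relative_expression(25, 20))
})

test_that("undetected wells give undefined expression, never zero", {
  expect_true(is.na(relative_expression(NA_real_, 20)))
  expect_true(is.na(relative_expression(25, NA_real_)))
  expect_error(relative_expression(-1, 20), "positive")
})

test_that("replicate aggregation averages detected wells", {
  expect_equal(aggregate_replicates(20), 20)
  expect_equal(aggregate_replicates(c(20, 22)), 21)
  # a partially detected replicate set counts as detected
  expect_equal(aggregate_replicates(c(NA, 30)), 30)
  expect_true(is.na(aggregate_replicates(c(NA_real_, NA_real_))))
  expect_error(aggregate_replicates(numeric()), "no replicate")
})

test_that("positivity is called from the total assay with inclusive cutoff", {
  expect_true(call_positivity_qpcr(28))
  expect_false(call_positivity_qpcr(NA_real_))
  expect_true(call_positivity_qpcr(40, max_cycles = 40))
  expect_false(call_positivity_qpcr(40.01, max_cycles = 40))
  expect_false(call_positivity_qpcr(36, max_cycles = 35))
})

test_that("variant percentages form a scale-invariant composition", {
  expect_equal(unname(variant_percentages(c(0.5, 0.25, 0.25))), c(50, 25, 25))
  expect_equal(unname(variant_percentages(c(0.2, 0.1, 0.1))), c(50, 25, 25))
  set.seed(11)
  for (i in 1:25) {
    e <- stats::rexp(3)
    pct <- variant_percentages(e)
    expect_equal(sum(pct), 100, tolerance = 1e-12)
    expect_equal(variant_percentages(e * stats::runif(1, 0.01, 100)), pct)
  }
  expect_true(all(is.na(variant_percentages(c(0, 0, 0)))))
  expect_true(all(is.na(variant_percentages(c(1, NA, 1)))))
})

test_that("the full qPCR build reproduces a hand-computed profile", {
  # NKp44-1/2/3 Ct (26, 28, 28) vs ACTB 20: expressions 2^-6, 2^-8, 2^-8,
  # hence percentages 4/6, 1/6, 1/6 of the variant sum
  tab <- ct_rows("s1", ACTB = 20, NKP44_TOTAL = 25,
                 NKP44_1 = 26, NKP44_2 = 28, NKP44_3 = 28)
  res <- build_qpcr_profiles(tab)
  p44 <- res$profiles[res$profiles$receptor == "NKP44", ]
  expect_true(p44$positive)
  expect_equal(c(p44$pct_v1, p44$pct_v2, p44$pct_v3),
               c(200 / 3, 50 / 3, 50 / 3))
  # beta-actin-normalised total retained as side output
  tot <- res$totals[res$totals$assay == "NKP44_TOTAL", ]
  expect_equal(tot$rel_expr, 2^-5)
})

test_that("qPCR build handles negatives, missing ACTB and empty tables", {
  tab <- rbind(
    ct_rows("neg", ACTB = 20, NKP44_TOTAL = NA, NKP44_1 = NA,
            NKP44_2 = NA, NKP44_3 = NA),
    ct_rows("noactb", NKP44_TOTAL = 25)
  )
  expect_warning(res <- build_qpcr_profiles(tab), "noactb")
  neg <- res$profiles[res$profiles$sample_id == "neg" &
                      res$profiles$receptor == "NKP44", ]
  expect_false(neg$positive)
  expect_true(is.na(neg$pct_v1))
  expect_identical(res$excluded, "noactb")
  empty <- build_qpcr_profiles(tab[0, ])
  expect_equal(nrow(empty$profiles), 0L)
})

test_that("Ct tables read back undetected flags and replicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,assay,ct,replicate",
               "s1,NKp44-total,25.1,1",
               "s1,NKp44-total,Undetermined,2",
               "s1,actb,20,1",
               "s1,actb,,2"), path)
  tab <- read_ct_table(path)
  expect_equal(tab$assay, c("NKP44_TOTAL", "NKP44_TOTAL", "ACTB", "ACTB"))
  expect_equal(tab$ct, c(25.1, NA, 20, NA))
  expect_error(read_ct_table_bad <- {
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,assay,ct,replicate", "s1,NOPE,20,1"), p2)
    read_ct_table(p2)
  }, "unknown assay")
})
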