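test_that("qPCR generator is seed-deterministic and respects limit cases", {
  spec <- qpcr_cohort_spec(n_samples = 12, seed = 99)
  a <- gen_qpcr_cohort(spec)
  b <- gen_qpcr_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(gen_qpcr_cohort(qpcr_cohort_spec(n_samples = 0))), 0L)
  all_pos <- gen_qpcr_cohort(qpcr_cohort_spec(n_samples = 50,
                                              positivity_rate = 1, seed = 3))
  expect_true(all(attr(all_pos, "truth")$positive))
  expect_error(qpcr_cohort_spec(dirichlet_dominant = c(1, 1, 1)),
               "expected v1")
  expect_error(qpcr_cohort_spec(dirichlet_nondominant = c(10, 1, 1)),
               "< 0.66")
})

test_that("generated Ct tables round-trip through the quantifier", {
  spec <- qpcr_cohort_spec(n_samples = 40, seed = 17)
  ct <- gen_qpcr_cohort(spec)
  expect_no_warning(prof <- build_qpcr_profiles(ct))
  p <- prof$profiles
  p$label <- classify_profiles(p)
  truth <- attr(ct, "truth")
  for (rec in c("NKP44", "NKP30")) {
    sub <- p[p$receptor == rec, ]
    want <- truth[[if (rec == "NKP44") "nkp44_class" else "nkp30_class"]]
    expect_equal(sub$label[match(truth$sample_id, sub$sample_id)], want)
  }
  # drawn fractions sit outside the boundary-exclusion band
  pos <- truth[truth$positive, ]
  expect_true(all(abs(100 * pos$f44_1 - 66) >= 1))
  expect_true(all(abs(100 * (pos$f30_a - pos$f30_c)) >= 1))
})

test_that("dominant fraction is recovered within binomial concentration", {
  spec <- qpcr_cohort_spec(n_samples = 400, positivity_rate = 1,
                           p_dominant = 0.8, seed = 101)
  ct <- gen_qpcr_cohort(spec)
  p <- build_qpcr_profiles(ct)$profiles
  lab <- classify_profiles(p[p$receptor == "NKP44", ])
  frac <- mean(lab == "NKP44_1_DOMINANT")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 400))
})

test_that("TCGA generator yields valid matched cohorts, byte-stable", {
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  spec <- tcga_cohort_spec(n_patients = 20, matched_fraction = 1, seed = 5)
  man_a <- gen_tcga_cohort(spec, dir_a)
  gen_tcga_cohort(spec, dir_b)
  files <- list.files(dir_a)
  expect_setequal(files, list.files(dir_b))
  for (f in files) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
  prof <- build_tcga_profiles(read_manifest(file.path(dir_a, "manifest.tsv")))
  expect_equal(nrow(prof$pairs), 20L)
  expect_equal(nrow(gen_tcga_cohort(tcga_cohort_spec(n_patients = 0),
                                    withr::local_tempdir())), 0L)
})

test_that("zero shift probability gives only identical defined pairs", {
  dir <- withr::local_tempdir()
  spec <- tcga_cohort_spec(n_patients = 30, matched_fraction = 1,
                           shift_probability = 0, seed = 8)
  gen_tcga_cohort(spec, dir)
  res <- run_tcga_arm(file.path(dir, "manifest.tsv"), withr::local_tempdir())
  expect_equal(res$shift_summary$n_non_identical, 0L)
  expect_equal(res$shift_summary$pct_identical, 100)
})

test_that("non-identical pair rate matches its closed-form expectation", {
  mix <- c(AB = 0.6, C = 0.4, NEGATIVE = 0)
  s_shift <- 0.7
  spec <- tcga_cohort_spec(n_patients = 500, matched_fraction = 1,
                           stn_profile_mix = mix, pst_profile_mix = mix,
                           shift_probability = s_shift, seed = 23)
  dir <- withr::local_tempdir()
  gen_tcga_cohort(spec, dir)
  res <- run_tcga_arm(file.path(dir, "manifest.tsv"), withr::local_tempdir())
  # PST differs from STN only when resampled to a different category:
  # P(non-identical) = s * (1 - sum(mix^2))
  p_expect <- s_shift * (1 - sum(mix^2))
  frac <- res$shift_summary$n_non_identical / res$shift_summary$n_defined
  expect_lt(abs(frac - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / 500))
})

test_that("generated barcodes round-trip patient and class at scale", {
  n <- 5000L
  patients <- sprintf("TCGA-SY-%04d", seq_len(n))
  barcodes <- c(sprintf("%s-01A-01T-%04d-07", patients, seq_len(n)),
                sprintf("%s-11A-01T-%04d-07", patients, seq_len(n)))
  bc <- parse_barcode(barcodes)
  expect_equal(bc$patient_id, rep(patients, 2))
  cls <- classify_sample(bc$sample_type_code)
  expect_equal(cls, rep(c("PST", "STN"), each = n))
  ann <- data.frame(raw = barcodes, patient_id = bc$patient_id,
                    sample_class = cls, stringsAsFactors = FALSE)
  pairs <- match_pairs(ann)
  expect_equal(nrow(pairs), n)
  expect_true(all(parse_barcode(pairs$pst_barcode)$patient_id ==
                  parse_barcode(pairs$stn_barcode)$patient_id))
})
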