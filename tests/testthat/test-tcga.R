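test_that("barcodes parse into patient, sample-type code and analyte", {
  bc <- parse_barcode("TCGA-AB-2842-03A-01T-0734-13")
  expect_equal(bc$patient_id, "TCGA-AB-2842")
  expect_equal(bc$sample_type_code, "03")
  expect_equal(bc$vial, "A")
  expect_equal(bc$analyte, "T")
  two <- parse_barcode(c("TCGA-AA-0001-01A-11R-A000-07",
                         "TCGA-AA-0001-11A-11R-A000-07"))
  expect_equal(two$sample_type_code, c("01", "11"))
  expect_error(parse_barcode("TCGA-AB-2842"), "malformed")
  expect_error(parse_barcode("TCGA-AB-2842-XYA-01T"), "sample-type")
})

test_that("sample classes partition the code space", {
  expect_equal(classify_sample(c("01", "11", "03", "06", "10")),
               c("PST", "STN", "EXCLUDED", "EXCLUDED", "EXCLUDED"))
  codes <- sprintf("%02d", 0:99)
  cls <- classify_sample(codes)
  expect_true(all(cls %in% c("PST", "STN", "EXCLUDED")))
  expect_equal(sum(cls == "PST"), 1L)
  expect_equal(sum(cls == "STN"), 1L)
})

test_that("cancer acronyms map to their organ clusters", {
  expect_equal(assign_cluster("BRCA"), "Breast")
  expect_equal(assign_cluster("CHOL"), "GIAccessory")
  expect_equal(assign_cluster(c("LUAD", "LUSC")), c("Lung", "Lung"))
  expect_equal(assign_cluster(c("CESC", "UCEC", "UCS")),
               rep("CervicalUterine", 3))
  expect_equal(assign_cluster(c("KICH", "KIRC", "KIRP")), rep("Kidney", 3))
  expect_equal(assign_cluster(c("COAD", "ESCA", "READ", "STAD")),
               rep("GITract", 4))
  expect_equal(assign_cluster(c("LIHC", "PAAD")), rep("GIAccessory", 2))
  expect_error(assign_cluster("ABCD"), "known codes")
})

test_that("RSEM positivity uses a strict threshold", {
  expect_false(call_positivity_rsem(0))
  expect_true(call_positivity_rsem(5.3))
  expect_false(call_positivity_rsem(0.5, epsilon = 1))
  expect_true(call_positivity_rsem(1.5, epsilon = 1))
})

test_that("isoform tables yield variant expressions; missing receptors flagged", {
  vm <- synthetic_variant_map()
  tab <- data.frame(
    feature_id = c("iso.NKp44.1", "iso.NKp44.2", "iso.NKp44.3", "junk"),
    normalized_count = c(2, 1, 1, 99), stringsAsFactors = FALSE)
  ex <- load_isoform_expressions(tab, vm)
  expect_equal(unname(variant_percentages(ex$NKP44)), c(50, 25, 25))
  expect_null(ex$NKP30)
  expect_null(load_isoform_expressions(tab[0, ], vm)$NKP44)
})

test_that("pair matching keeps one deterministic pair per matched patient", {
  ann <- data.frame(
    raw = c("TCGA-SY-0001-01A-01T-0001-07", "TCGA-SY-0001-11A-01T-0001-07",
            "TCGA-SY-0002-01A-01T-0002-07",
            "TCGA-SY-0003-01A-01T-0003-07", "TCGA-SY-0003-11B-01T-0003-07",
            "TCGA-SY-0003-11A-01T-0003-07"),
    stringsAsFactors = FALSE)
  ann <- cbind(ann, parse_barcode(ann$raw)[c("patient_id")])
  ann$sample_class <- classify_sample(parse_barcode(ann$raw)$sample_type_code)
  pairs <- match_pairs(ann)
  expect_equal(nrow(pairs), 2L)
  expect_false("TCGA-SY-0002" %in% pairs$patient_id)
  # duplicate STN aliquots resolve to the lexicographically smallest barcode
  expect_equal(pairs$stn_barcode[pairs$patient_id == "TCGA-SY-0003"],
               "TCGA-SY-0003-11A-01T-0003-07")
  expect_true(all(parse_barcode(pairs$stn_barcode)$patient_id ==
                  pairs$patient_id))
})

test_that("generated TCGA cohorts ingest cleanly and recover their labels", {
  dir <- withr::local_tempdir()
  spec <- tcga_cohort_spec(n_patients = 25, matched_fraction = 1,
                           shift_probability = 0.4, seed = 42)
  man <- gen_tcga_cohort(spec, dir)
  expect_no_warning(prof <- build_tcga_profiles(read_manifest(
    file.path(dir, "manifest.tsv"))))
  truth <- attr(man, "truth")
  expect_equal(nrow(prof$pairs), sum(truth$matched))
  p <- prof$profiles
  p$label <- classify_profiles(p)
  p30 <- p[p$receptor == "NKP30" & p$sample_class == "PST", ]
  got <- p30$label[match(truth$patient_id, p30$patient_id)]
  want <- c(AB = "NKP30_AB", C = "NKP30_C", NEGATIVE = "NEGATIVE")[truth$pst_cat]
  expect_equal(got, unname(want))
})
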