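# Study-arm runners: bind quantification, classification and statistics
# into the decidua-qPCR arm and the TCGA-tumor arm, and emit tables.

pkg_version <- function() {
  as.character(utils::packageVersion("ncrprofile"))
}

# Polynomial rolling hash (mod 2^31 - 1) of a deparsed configuration, for
# table provenance headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ncrprofile %s config=%s", pkg_version(),
                     config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

round2 <- function(x) round(x, 2)

#' Run the decidua-qPCR study arm
#'
#' Quantifies a Ct table, classifies each sample's NKp44 and NKp30 profile,
#' and writes per-clinical-group incidence tables, profile distributions and
#' all pairwise two-sided Fisher exact tests. Mirrors the decidua analysis:
#' positivity incidence per group, NKp44-1-dominant vs NKp44-2/3
#' distribution among positive cases, and NKp30a/b vs NKp30c distribution.
#'
#' @param ct_table Path to a Ct table (see [read_ct_table()]) or an
#'   equivalent data frame.
#' @param groups Path to a two-column table `sample_id`, `group` (CSV/TSV by
#'   extension) or an equivalent data frame. Samples absent from the group
#'   table are excluded with a warning, as are group entries with unknown
#'   sample ids.
#' @param out_dir Output directory.
#' @param config A [classifier_config()].
#' @param max_cycles qPCR positivity cutoff (cycles).
#' @return Invisibly, a list with the computed tables (`incidence`,
#'   `nkp44_distribution`, `nkp30_distribution`, `fisher_tests`) and the
#'   paths written.
#' @export
run_qpcr_arm <- function(ct_table, groups, out_dir,
                         config = classifier_config(), max_cycles = 40) {
  if (is.character(ct_table)) ct_table <- read_ct_table(ct_table)
  if (nrow(ct_table) == 0L) stop("empty Ct table", call. = FALSE)
  if (is.character(groups)) {
    sep <- if (grepl("\\.(tsv|txt)$", groups, ignore.case = TRUE)) "\t" else ","
    groups <- utils::read.table(groups, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  unknown <- setdiff(groups$sample_id, unique(ct_table$sample_id))
  if (length(unknown)) {
    warning("group assignments for unknown sample id(s) ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    groups <- groups[!groups$sample_id %in% unknown, , drop = FALSE]
  }
  prof <- build_qpcr_profiles(ct_table, max_cycles = max_cycles)
  p <- prof$profiles
  p$group <- groups$group[match(p$sample_id, groups$sample_id)]
  ungrouped <- unique(p$sample_id[is.na(p$group)])
  if (length(ungrouped)) {
    warning("sample(s) without group assignment excluded: ",
            paste(ungrouped, collapse = ", "), call. = FALSE)
    p <- p[!is.na(p$group), , drop = FALSE]
  }
  p$label <- classify_profiles(p, config)

  run_cfg <- list(config = unclass(config), max_cycles = max_cycles)
  grps <- unique(p$group)
  inc <- do.call(rbind, unlist(lapply(RECEPTORS, function(rec) {
    lapply(grps, function(g) {
      row <- incidence(p$label[p$receptor == rec & p$group == g], g)
      cbind(receptor = rec, row)
    })
  }), recursive = FALSE))
  inc$percent_positive <- round2(inc$percent_positive)

  dist_for <- function(rec) {
    out <- lapply(grps, function(g) {
      lab <- p$label[p$receptor == rec & p$group == g]
      if (all(lab == "NEGATIVE")) return(NULL)
      profile_distribution(lab, g)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (!is.null(out)) out$percent <- round2(out$percent)
    out
  }
  d44 <- dist_for("NKP44")
  d30 <- dist_for("NKP30")

  # all pairwise group comparisons: positivity incidence and, per receptor,
  # the two-category profile split among positive cases
  tests <- list()
  add_test <- function(what, rec, g1, g2, c1, c2) {
    if (sum(c1) == 0 || sum(c2) == 0) return()
    res <- compare_groups(c1, c2)
    tests[[length(tests) + 1L]] <<- data.frame(
      comparison = what, receptor = rec, group_a = g1, group_b = g2,
      a = c1[1L], b = c1[2L], c = c2[1L], d = c2[2L],
      p_value = res$test$p_value,
      significance = if (res$test$p_value < 0.01) "**"
                     else if (res$test$p_value < 0.05) "*" else "NS",
      stringsAsFactors = FALSE)
  }
  cat_of <- list(NKP44 = c("NKP44_1_DOMINANT", "NKP44_2_3"),
                 NKP30 = c("NKP30_AB", "NKP30_C"))
  if (length(grps) >= 2L) {
    pairs <- utils::combn(grps, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (rec in RECEPTORS) {
        l1 <- p$label[p$receptor == rec & p$group == pr[1L]]
        l2 <- p$label[p$receptor == rec & p$group == pr[2L]]
        add_test("incidence", rec, pr[1L], pr[2L],
                 c(sum(l1 != "NEGATIVE"), sum(l1 == "NEGATIVE")),
                 c(sum(l2 != "NEGATIVE"), sum(l2 == "NEGATIVE")))
        add_test("profile", rec, pr[1L], pr[2L],
                 label_counts(l1, cat_of[[rec]]),
                 label_counts(l2, cat_of[[rec]]))
      }
    }
  }
  fisher <- if (length(tests)) do.call(rbind, tests) else NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(incidence = file.path(out_dir, "incidence.tsv"),
             nkp44 = file.path(out_dir, "nkp44_profile_distribution.tsv"),
             nkp30 = file.path(out_dir, "nkp30_profile_distribution.tsv"),
             fisher = file.path(out_dir, "fisher_tests.tsv"),
             totals = file.path(out_dir, "actb_normalized_totals.tsv"))
  write_report_table(inc, paths[["incidence"]], run_cfg)
  if (!is.null(d44)) write_report_table(d44, paths[["nkp44"]], run_cfg)
  if (!is.null(d30)) write_report_table(d30, paths[["nkp30"]], run_cfg)
  if (!is.null(fisher)) write_report_table(fisher, paths[["fisher"]], run_cfg)
  write_report_table(prof$totals, paths[["totals"]], run_cfg)
  report <- list(incidence = inc, nkp44_distribution = d44,
                 nkp30_distribution = d30, fisher_tests = fisher,
                 n_tests = if (is.null(fisher)) 0L else nrow(fisher),
                 profiles = p, paths = paths)
  jsonlite::write_json(
    report[c("incidence", "nkp44_distribution", "nkp30_distribution",
             "fisher_tests", "n_tests")],
    file.path(out_dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(report)
}

#' Run the TCGA-style study arm
#'
#' Ingests a manifest of RSEM files, classifies profiles, and writes the
#' tumor analyses: per-cluster NKp44 incidence in primary solid tumor (PST)
#' vs matched solid-tissue-normal (STN) with Fisher tests; NKp44 profile
#' distribution among positive total-PST cases; NKp30 three-way
#' distributions for total PST, matched PST and matched STN; and the
#' matched-pair NKp30 shift summary (identical vs non-identical, and the
#' shift directions with non-defined pairs reported separately).
#'
#' @param manifest Path to a manifest TSV (see [read_manifest()]) or an
#'   equivalent data frame.
#' @param out_dir Output directory.
#' @param variant_map Path to a variant-map TSV or a data frame; defaults to
#'   the package's synthetic map.
#' @param epsilon RSEM positivity threshold.
#' @param config A [classifier_config()].
#' @return Invisibly, a list of the computed tables and paths.
#' @export
run_tcga_arm <- function(manifest, out_dir,
                         variant_map = synthetic_variant_map(),
                         epsilon = 0, config = classifier_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(variant_map)) variant_map <- read_variant_map(variant_map)
  prof <- build_tcga_profiles(manifest, variant_map, epsilon = epsilon)
  p <- prof$profiles
  p$label <- classify_profiles(p, config)
  run_cfg <- list(config = unclass(config), epsilon = epsilon)

  clusters <- unique(p$cluster)
  # per-cluster NKp44 incidence, PST vs STN, with Fisher
  inc_rows <- list()
  for (cl in clusters) {
    for (scls in c("PST", "STN")) {
      lab <- p$label[p$receptor == "NKP44" & p$cluster == cl &
                     p$sample_class == scls]
      if (length(lab) == 0L) next
      row <- incidence(lab, paste(cl, scls, sep = "/"))
      inc_rows[[length(inc_rows) + 1L]] <-
        cbind(cluster = cl, sample_class = scls, row)
    }
  }
  inc44 <- if (length(inc_rows)) do.call(rbind, inc_rows) else NULL
  if (!is.null(inc44)) inc44$percent_positive <- round2(inc44$percent_positive)

  fisher_rows <- list()
  for (cl in clusters) {
    lp <- p$label[p$receptor == "NKP44" & p$cluster == cl &
                  p$sample_class == "PST"]
    ls <- p$label[p$receptor == "NKP44" & p$cluster == cl &
                  p$sample_class == "STN"]
    if (length(lp) == 0L || length(ls) == 0L) next
    res <- compare_groups(c(sum(lp != "NEGATIVE"), sum(lp == "NEGATIVE")),
                          c(sum(ls != "NEGATIVE"), sum(ls == "NEGATIVE")))
    fisher_rows[[length(fisher_rows) + 1L]] <- data.frame(
      cluster = cl, comparison = "NKp44 incidence PST vs STN",
      p_value = res$test$p_value, stringsAsFactors = FALSE)
  }
  fisher44 <- if (length(fisher_rows)) do.call(rbind, fisher_rows) else NULL

  # NKp44 profile distribution among positive total-PST cases
  d44_rows <- lapply(clusters, function(cl) {
    lab <- p$label[p$receptor == "NKP44" & p$cluster == cl &
                   p$sample_class == "PST"]
    if (length(lab) == 0L || all(lab == "NEGATIVE")) return(NULL)
    profile_distribution(lab, cl)
  })
  d44 <- do.call(rbind, d44_rows[!vapply(d44_rows, is.null, logical(1))])
  if (!is.null(d44)) d44$percent <- round2(d44$percent)

  # NKp30 distributions: total PST / matched PST / matched STN, with the
  # negative fraction reported alongside (denominator = all samples in the
  # set, as the three-way bars include the negative cases)
  matched_pst <- prof$pairs$pst_barcode
  matched_stn <- prof$pairs$stn_barcode
  sets <- list(total_PST = p$sample_class == "PST",
               matched_PST = p$barcode %in% matched_pst,
               matched_STN = p$barcode %in% matched_stn)
  d30_rows <- list()
  for (cl in clusters) {
    for (sn in names(sets)) {
      sel <- p$receptor == "NKP30" & p$cluster == cl & sets[[sn]]
      lab <- p$label[sel]
      if (length(lab) == 0L) next
      tab <- table(factor(lab, levels = c("NKP30_AB", "NKP30_C", "NEGATIVE")))
      d30_rows[[length(d30_rows) + 1L]] <- data.frame(
        cluster = cl, set = sn, label = names(tab),
        count = as.integer(tab),
        percent = round2(100 * as.integer(tab) / length(lab)),
        stringsAsFactors = FALSE)
    }
  }
  d30 <- if (length(d30_rows)) do.call(rbind, d30_rows) else NULL

  # matched-pair NKp30 shift typing
  shift <- NULL; shift_summary <- NULL
  if (nrow(prof$pairs)) {
    lab_of <- function(bc) {
      p$label[p$receptor == "NKP30"][match(bc, p$barcode[p$receptor == "NKP30"])]
    }
    sh <- classify_shift(lab_of(prof$pairs$stn_barcode),
                         lab_of(prof$pairs$pst_barcode))
    shift <- cbind(prof$pairs["patient_id"], sh)
    defined <- !is.na(shift$identity)
    n_def <- sum(defined)
    shift_summary <- data.frame(
      n_pairs = nrow(shift),
      n_defined = n_def,
      n_identical = sum(shift$identity == "IDENTICAL", na.rm = TRUE),
      n_non_identical = sum(shift$identity == "NON_IDENTICAL", na.rm = TRUE),
      pct_identical = if (n_def) round2(100 * sum(shift$identity == "IDENTICAL",
                                                  na.rm = TRUE) / n_def) else NA_real_,
      n_ab_to_c = sum(shift$direction == "AB_TO_C"),
      n_c_to_ab = sum(shift$direction == "C_TO_AB"),
      n_non_defined = sum(shift$direction == "NON_DEFINED"),
      stringsAsFactors = FALSE)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(incidence = file.path(out_dir, "nkp44_incidence.tsv"),
             fisher = file.path(out_dir, "nkp44_incidence_fisher.tsv"),
             nkp44 = file.path(out_dir, "nkp44_pst_profiles.tsv"),
             nkp30 = file.path(out_dir, "nkp30_distributions.tsv"),
             shift = file.path(out_dir, "nkp30_shift_calls.tsv"),
             shift_summary = file.path(out_dir, "nkp30_shift_summary.tsv"))
  if (!is.null(inc44)) write_report_table(inc44, paths[["incidence"]], run_cfg)
  if (!is.null(fisher44)) write_report_table(fisher44, paths[["fisher"]], run_cfg)
  if (!is.null(d44)) write_report_table(d44, paths[["nkp44"]], run_cfg)
  if (!is.null(d30)) write_report_table(d30, paths[["nkp30"]], run_cfg)
  if (!is.null(shift)) {
    write_report_table(shift, paths[["shift"]], run_cfg)
    write_report_table(shift_summary, paths[["shift_summary"]], run_cfg)
  }
  invisible(list(incidence_nkp44 = inc44, fisher_nkp44 = fisher44,
                 nkp44_pst_distribution = d44, nkp30_distributions = d30,
                 shift_calls = shift, shift_summary = shift_summary,
                 profiles = p, pairs = prof$pairs, paths = paths))
}

#' Generate synthetic fixtures on disk with provenance
#'
#' Runs the synthetic generators and writes their outputs plus a provenance
#' JSON (the spec, seed and package version). `spec` may be a
#' [qpcr_cohort_spec()] or a [tcga_cohort_spec()].
#'
#' @param spec A cohort spec object.
#' @param out_dir Output directory.
#' @return Invisibly, the generated table/manifest.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(spec, "qpcr_cohort_spec")) {
    tab <- gen_qpcr_cohort(spec)
    out <- tab
    out$ct <- ifelse(is.na(out$ct), "Undetermined", sprintf("%.6f", out$ct))
    utils::write.table(out, file.path(out_dir, "ct_table.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    kind <- "qpcr"
  } else if (inherits(spec, "tcga_cohort_spec")) {
    tab <- gen_tcga_cohort(spec, out_dir)
    kind <- "tcga"
  } else {
    stop("spec must be a qpcr_cohort_spec or tcga_cohort_spec", call. = FALSE)
  }
  jsonlite::write_json(
    list(kind = kind, spec = unclass(spec), seed = spec$seed,
         version = pkg_version()),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
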