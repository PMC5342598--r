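# TCGA-style ingest: barcode parsing, sample classification, organ
# clustering, RSEM table loading, matched tumor/normal pairing.

# Organ-of-origin clusters for the TCGA study codes used in the analysis.
DEFAULT_CLUSTER_MAP <- c(
  BRCA = "Breast",
  LUAD = "Lung", LUSC = "Lung",
  CESC = "CervicalUterine", UCEC = "CervicalUterine", UCS = "CervicalUterine",
  KICH = "Kidney", KIRC = "Kidney", KIRP = "Kidney",
  COAD = "GITract", ESCA = "GITract", READ = "GITract", STAD = "GITract",
  CHOL = "GIAccessory", LIHC = "GIAccessory", PAAD = "GIAccessory"
)

#' Parse a TCGA sample/aliquot barcode
#'
#' Splits a barcode such as `TCGA-AB-2842-03A-01T-0734-13` on dashes. The
#' patient identifier is the first three sections joined
#' (`TCGA-AB-2842`); the two-digit sample-type code is the leading pair of
#' digits of the fourth section (`03` from `03A`), with the trailing letter
#' of that section kept as the vial; the analyte letter, when present, is the
#' trailing letter of the fifth section (`T` = total RNA).
#'
#' @param raw Character vector of barcodes (>= 4 dash-separated sections).
#' @return A data frame with columns `raw`, `patient_id`, `sample_type_code`,
#'   `vial`, `analyte` (`NA` when absent).
#' @export
#' @examples
#' parse_barcode("TCGA-AB-2842-03A-01T-0734-13")
parse_barcode <- function(raw) {
  stopifnot(is.character(raw))
  parts <- strsplit(raw, "-", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 4L
  if (any(bad)) {
    stop("malformed TCGA barcode(s): ", paste(raw[bad], collapse = ", "),
         " (need >= 4 dash-separated sections)", call. = FALSE)
  }
  code <- vapply(parts, function(p) substr(p[4L], 1L, 2L), character(1))
  ok <- grepl("^[0-9]{2}$", code)
  if (any(!ok)) {
    stop("malformed sample-type section in barcode(s): ",
         paste(raw[!ok], collapse = ", "), call. = FALSE)
  }
  vial <- vapply(parts, function(p) {
    v <- sub("^[0-9]+", "", p[4L])
    if (nzchar(v)) v else NA_character_
  }, character(1))
  analyte <- vapply(parts, function(p) {
    if (length(p) < 5L) return(NA_character_)
    a <- sub("^[0-9]+", "", p[5L])
    if (nzchar(a)) a else NA_character_
  }, character(1))
  data.frame(
    raw = raw,
    patient_id = vapply(parts, function(p) paste(p[1:3], collapse = "-"),
                        character(1)),
    sample_type_code = code,
    vial = vial,
    analyte = analyte,
    stringsAsFactors = FALSE
  )
}

#' Classify a TCGA sample-type code
#'
#' Only two sample types enter the analysis: `01` = Primary Solid Tumor
#' (PST) and `11` = Solid Tissue Normal (STN). Every other code is
#' `EXCLUDED`.
#'
#' @param code Character vector of two-digit sample-type codes.
#' @return Character vector over `{"PST", "STN", "EXCLUDED"}`.
#' @export
classify_sample <- function(code) {
  stopifnot(is.character(code))
  ifelse(code == "01", "PST", ifelse(code == "11", "STN", "EXCLUDED"))
}

#' Map a TCGA study acronym to its organ cluster
#'
#' @param acronym Character vector of TCGA study codes (e.g. `"BRCA"`).
#' @param cluster_map Named character vector acronym -> cluster; defaults to
#'   the study's organ-of-origin grouping (Breast; Lung; CervicalUterine;
#'   Kidney; GITract; GIAccessory).
#' @return Character vector of cluster labels.
#' @export
#' @examples
#' assign_cluster(c("BRCA", "CHOL"))
assign_cluster <- function(acronym, cluster_map = DEFAULT_CLUSTER_MAP) {
  stopifnot(is.character(acronym))
  unknown <- setdiff(unique(acronym), names(cluster_map))
  if (length(unknown)) {
    stop("unknown cancer acronym(s): ", paste(unknown, collapse = ", "),
         "; known codes: ", paste(names(cluster_map), collapse = ", "),
         call. = FALSE)
  }
  unname(cluster_map[acronym])
}

#' Read an isoform-to-variant map
#'
#' The map ships as an editable TSV with columns `isoform_id`, `receptor`,
#' `variant` because transcript identifiers differ between annotation
#' releases. Each isoform maps to exactly one variant and each receptor must
#' have exactly three variants mapped.
#'
#' @param path Path to the TSV.
#' @return Data frame `isoform_id`, `receptor`, `variant`.
#' @export
read_variant_map <- function(path) {
  vm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("isoform_id", "receptor", "variant")
  if (!all(need %in% names(vm))) {
    stop("variant map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vm$receptor <- toupper(vm$receptor)
  if (anyDuplicated(vm$isoform_id)) {
    stop("variant map assigns an isoform to more than one variant",
         call. = FALSE)
  }
  n_per <- table(vm$receptor)
  if (any(n_per != 3L)) {
    stop("variant map must list exactly 3 variants per receptor", call. = FALSE)
  }
  vm
}

#' Built-in synthetic isoform-to-variant map
#'
#' Synthetic isoform identifiers used by the cohort generator and the test
#' fixtures. Real transcript IDs are annotation-dependent, so analyses of
#' real data supply their own map via [read_variant_map()].
#'
#' @return Data frame `isoform_id`, `receptor`, `variant`.
#' @export
synthetic_variant_map <- function() {
  data.frame(
    isoform_id = c("iso.NKp44.1", "iso.NKp44.2", "iso.NKp44.3",
                   "iso.NKp30.a", "iso.NKp30.b", "iso.NKp30.c"),
    receptor = c("NKP44", "NKP44", "NKP44", "NKP30", "NKP30", "NKP30"),
    variant = c("NKP44_1", "NKP44_2", "NKP44_3",
                "NKP30_A", "NKP30_B", "NKP30_C"),
    stringsAsFactors = FALSE
  )
}

synthetic_gene_ids <- c(NKP44 = "NCR2|9436", NKP30 = "NCR3|259197",
                        NKP46 = "NCR1|9437")

#' Load an RSEM-style normalized results table
#'
#' Reads a tab-separated file with a header line; the first column is taken
#' as the feature identifier (`isoform_id` or `gene_id`) and the
#' `normalized_count` column as the normalized RSEM expression. Additional
#' RSEM columns are tolerated and ignored.
#'
#' @param path Path to the file.
#' @return Data frame `feature_id`, `normalized_count`.
#' @export
read_rsem_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) {
    return(data.frame(feature_id = character(), normalized_count = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!"normalized_count" %in% names(tab)) {
    stop("RSEM table ", path, " has no normalized_count column", call. = FALSE)
  }
  cnt <- as.numeric(tab$normalized_count)
  if (any(is.na(cnt) | cnt < 0)) {
    stop("RSEM normalized counts must be non-negative numbers: ", path,
         call. = FALSE)
  }
  data.frame(feature_id = as.character(tab[[1L]]), normalized_count = cnt,
             stringsAsFactors = FALSE)
}

#' Extract per-receptor variant expressions from an isoform table
#'
#' Rows whose identifier is not in the variant map are ignored. A receptor
#' with no mapped isoform present in the table is reported as missing
#' (`NULL` entry) rather than zero.
#'
#' @param isoform_table Data frame from [read_rsem_table()].
#' @param variant_map Data frame from [read_variant_map()] (defaults to the
#'   package's synthetic map).
#' @return Named list per receptor; each element a named numeric vector of
#'   variant normalized counts in variant order, or `NULL` if the receptor's
#'   isoforms are absent from the table.
#' @export
load_isoform_expressions <- function(isoform_table,
                                     variant_map = synthetic_variant_map()) {
  out <- list()
  for (rec in unique(variant_map$receptor)) {
    vm <- variant_map[variant_map$receptor == rec, ]
    vm <- vm[order(vm$variant), ]
    idx <- match(vm$isoform_id, isoform_table$feature_id)
    if (all(is.na(idx))) {
      out[rec] <- list(NULL)
      next
    }
    vals <- isoform_table$normalized_count[idx]
    vals[is.na(vals)] <- NA_real_
    names(vals) <- vm$variant
    out[[rec]] <- vals
  }
  out
}

#' Call mRNA positivity from a gene-level RSEM value
#'
#' @param normalized_count Gene-level normalized count(s).
#' @param epsilon Positivity threshold: positive iff count strictly exceeds
#'   `epsilon`. The default 0 is the permissive rule a normalized RSEM value
#'   supports (any nonzero evidence of expression counts as positive).
#' @return Logical vector.
#' @export
call_positivity_rsem <- function(normalized_count, epsilon = 0) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  !is.na(normalized_count) & normalized_count > epsilon
}

#' Match tumor/normal sample pairs within patients
#'
#' Builds one (STN, PST) pair for every patient contributing both sample
#' classes. Patients lacking either class are excluded from paired analyses
#' (but remain in total-PST analyses upstream). When a patient has several
#' aliquots of one class, the lexicographically smallest barcode is chosen,
#' which makes pairing deterministic.
#'
#' @param annotations Data frame with columns `raw` (barcode), `patient_id`,
#'   `sample_class` (`"PST"`/`"STN"`/`"EXCLUDED"`).
#' @return Data frame `patient_id`, `stn_barcode`, `pst_barcode`, one row per
#'   matched patient, ordered by `patient_id`.
#' @export
match_pairs <- function(annotations) {
  stopifnot(all(c("raw", "patient_id", "sample_class") %in% names(annotations)))
  ann <- annotations[annotations$sample_class %in% c("PST", "STN"), ]
  pick_min <- function(df) {
    vapply(split(df$raw, df$patient_id), min, character(1))
  }
  stn <- pick_min(ann[ann$sample_class == "STN", ])
  pst <- pick_min(ann[ann$sample_class == "PST", ])
  patients <- sort(intersect(names(stn), names(pst)))
  data.frame(patient_id = patients,
             stn_barcode = unname(stn[patients]),
             pst_barcode = unname(pst[patients]),
             stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV mapping each sample to its expression files:
#' columns `barcode`, `cancer_acronym`, `isoform_path`, `gene_path`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return Data frame with the four columns, paths made absolute.
#' @export
read_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("barcode", "cancer_acronym", "isoform_path", "gene_path")
  if (!all(need %in% names(man))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  man$isoform_path <- fix(man$isoform_path)
  man$gene_path <- fix(man$gene_path)
  man
}

#' Build receptor profiles for a TCGA-style cohort
#'
#' For each manifest sample: parses and classifies the barcode, assigns the
#' organ cluster, calls gene-level positivity per receptor, and computes
#' splice-variant percentages from the isoform table (percentages are each
#' variant's normalized count divided by the summed receptor counts).
#' Samples whose sample-type code is neither 01 nor 11 are dropped.
#'
#' @param manifest Data frame from [read_manifest()].
#' @param variant_map Data frame from [read_variant_map()].
#' @param epsilon Gene-level positivity threshold, see
#'   [call_positivity_rsem()].
#' @param cluster_map See [assign_cluster()].
#' @return An object of class `tcga_profiles`: list with `profiles` (data
#'   frame `barcode`, `patient_id`, `sample_class`, `cancer_acronym`,
#'   `cluster`, `receptor`, `positive`, `pct_v1..3`), `pairs` (from
#'   [match_pairs()]) and `n_excluded` (samples outside 01/11).
#' @export
build_tcga_profiles <- function(manifest, variant_map = synthetic_variant_map(),
                                epsilon = 0,
                                cluster_map = DEFAULT_CLUSTER_MAP) {
  stopifnot(is.data.frame(manifest))
  bc <- parse_barcode(manifest$barcode)
  cls <- classify_sample(bc$sample_type_code)
  keep <- cls %in% c("PST", "STN")
  n_excluded <- sum(!keep)
  man <- manifest[keep, , drop = FALSE]
  bc <- bc[keep, , drop = FALSE]
  cls <- cls[keep]

  rows <- list()
  for (i in seq_len(nrow(man))) {
    iso <- read_rsem_table(man$isoform_path[i])
    gene <- read_rsem_table(man$gene_path[i])
    exprs <- load_isoform_expressions(iso, variant_map)
    for (rec in unique(variant_map$receptor)) {
      gid <- synthetic_gene_ids[[rec]]
      gval <- gene$normalized_count[match(gid, gene$feature_id)]
      if (is.na(gval) && !is.null(exprs[[rec]]) && !anyNA(exprs[[rec]])) {
        # no gene-level row (or non-synthetic gene id): fall back to the
        # summed isoform counts as the gene-level abundance
        gval <- sum(exprs[[rec]])
      }
      positive <- call_positivity_rsem(gval, epsilon)
      pct <- rep(NA_real_, 3L)
      if (positive && !is.null(exprs[[rec]]) && !anyNA(exprs[[rec]])) {
        pct <- unname(variant_percentages(exprs[[rec]]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = man$barcode[i], patient_id = bc$patient_id[i],
        sample_class = cls[i], cancer_acronym = man$cancer_acronym[i],
        cluster = assign_cluster(man$cancer_acronym[i], cluster_map),
        receptor = rec, positive = positive,
        pct_v1 = pct[1L], pct_v2 = pct[2L], pct_v3 = pct[3L],
        stringsAsFactors = FALSE
      )
    }
  }
  profiles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(barcode = character(), patient_id = character(),
               sample_class = character(), cancer_acronym = character(),
               cluster = character(), receptor = character(),
               positive = logical(), pct_v1 = numeric(), pct_v2 = numeric(),
               pct_v3 = numeric(), stringsAsFactors = FALSE)
  ann <- unique(data.frame(raw = profiles$barcode,
                           patient_id = profiles$patient_id,
                           sample_class = profiles$sample_class,
                           stringsAsFactors = FALSE))
  structure(list(profiles = profiles, pairs = match_pairs(ann),
                 n_excluded = n_excluded),
            class = "tcga_profiles")
}

#' @export
print.tcga_profiles <- function(x, ...) {
  p <- x$profiles
  cat("TCGA-style cohort profiles:",
      length(unique(p$barcode)), "sample(s),",
      nrow(x$pairs), "matched pair(s),",
      x$n_excluded, "excluded\n")
  if (nrow(p)) {
    tab <- table(p$sample_class[p$receptor == p$receptor[1L]])
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
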