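# Synthetic cohorts: qPCR Ct tables and TCGA-like RSEM file sets with
# known profile mixtures, positivity dropout and matched pairs, so every
# pipeline stage is testable without external downloads.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Redraw compositions until they sit outside the classifier's decision
# band: |100*f1 - threshold| >= band for the dominance rule, or
# |%a - %c| >= band for the a-vs-c rule. Keeps generated labels exactly
# recoverable by the classifiers.
draw_fraction_nkp44 <- function(alpha, dominant, threshold = 66, band = 1) {
  repeat {
    f <- rdirichlet1(alpha)
    p1 <- 100 * f[1L]
    if (band > 0 && abs(p1 - threshold) < band) next
    if (dominant && p1 < threshold) next
    if (!dominant && p1 >= threshold) next
    return(f)
  }
}

draw_fraction_nkp30 <- function(alpha, ab, band = 1) {
  repeat {
    f <- rdirichlet1(alpha)
    gap <- 100 * (f[1L] - f[3L])
    if (band > 0 && abs(gap) < band) next
    if (ab && gap < 0) next
    if (!ab && gap >= 0) next
    return(f)
  }
}

#' Specification of a synthetic qPCR cohort
#'
#' Defines the sampling model for a decidua-style qPCR cohort: each sample
#' is receptor-positive with `positivity_rate`; a positive sample is
#' NKp44-1-dominant with `p_dominant` and its (v1, v2, v3) fractions are
#' drawn from the class-conditional Dirichlet (`dirichlet_dominant` /
#' `dirichlet_nondominant`); analogously the NKp30 profile is a/b with
#' `p_ab` using `dirichlet_ab` / `dirichlet_c`. Ct values are back-computed
#' so the 2^-dCt expressions reproduce the drawn fractions, with ACTB Ct
#' drawn from N(`ct_reference_mean`, `ct_reference_sd`) and optional
#' per-well Gaussian jitter of `noise_sd` cycles. Negative samples have all
#' receptor wells undetected. Fractions are redrawn to stay at least
#' `boundary_band` percentage points away from the 66% (and %a = %c)
#' decision boundaries so generated labels are exactly recoverable; set
#' `boundary_band = 0` to disable.
#'
#' @param n_samples Number of samples.
#' @param positivity_rate Probability a sample is receptor-positive.
#' @param p_dominant Probability a positive sample is NKp44-1-dominant.
#' @param dirichlet_dominant,dirichlet_nondominant Concentration triplets
#'   for (v1, v2, v3); the dominant class must have expected v1 fraction
#'   >= 0.66 and the non-dominant class < 0.66.
#' @param p_ab Probability a positive sample has an NKp30a/b profile.
#' @param dirichlet_ab,dirichlet_c Concentration triplets for (a, b, c).
#' @param ct_reference_mean,ct_reference_sd ACTB Ct distribution (cycles).
#' @param noise_sd Per-well Ct jitter (cycles); default 0.
#' @param boundary_band Decision-boundary exclusion band in percentage
#'   points; default 1.
#' @param seed Integer RNG seed; one RNG stream per generator call.
#' @return A list of class `qpcr_cohort_spec`.
#' @export
qpcr_cohort_spec <- function(n_samples = 20, positivity_rate = 0.9,
                             p_dominant = 0.8,
                             dirichlet_dominant = c(16, 2, 2),
                             dirichlet_nondominant = c(4, 8, 8),
                             p_ab = 0.6,
                             dirichlet_ab = c(10, 4, 4),
                             dirichlet_c = c(4, 4, 10),
                             ct_reference_mean = 18, ct_reference_sd = 1,
                             noise_sd = 0, boundary_band = 1, seed = 1L) {
  spec <- list(n_samples = n_samples, positivity_rate = positivity_rate,
               p_dominant = p_dominant,
               dirichlet_dominant = dirichlet_dominant,
               dirichlet_nondominant = dirichlet_nondominant,
               p_ab = p_ab, dirichlet_ab = dirichlet_ab,
               dirichlet_c = dirichlet_c,
               ct_reference_mean = ct_reference_mean,
               ct_reference_sd = ct_reference_sd,
               noise_sd = noise_sd, boundary_band = boundary_band,
               seed = as.integer(seed))
  validate_qpcr_spec(spec)
  structure(spec, class = "qpcr_cohort_spec")
}

validate_qpcr_spec <- function(s) {
  stopifnot(s$n_samples >= 0,
            s$positivity_rate >= 0, s$positivity_rate <= 1,
            s$p_dominant >= 0, s$p_dominant <= 1,
            s$p_ab >= 0, s$p_ab <= 1,
            length(s$dirichlet_dominant) == 3L, all(s$dirichlet_dominant > 0),
            length(s$dirichlet_nondominant) == 3L,
            all(s$dirichlet_nondominant > 0),
            length(s$dirichlet_ab) == 3L, all(s$dirichlet_ab > 0),
            length(s$dirichlet_c) == 3L, all(s$dirichlet_c > 0),
            s$ct_reference_sd >= 0, s$noise_sd >= 0, s$boundary_band >= 0)
  if (s$dirichlet_dominant[1L] / sum(s$dirichlet_dominant) < 0.66) {
    stop("dominant-class Dirichlet must have expected v1 fraction >= 0.66",
         call. = FALSE)
  }
  if (s$dirichlet_nondominant[1L] / sum(s$dirichlet_nondominant) >= 0.66) {
    stop("non-dominant-class Dirichlet must have expected v1 fraction < 0.66",
         call. = FALSE)
  }
  invisible(s)
}

#' Generate a synthetic qPCR Ct table
#'
#' Draws a cohort under a [qpcr_cohort_spec()] and emits a long-format Ct
#' table in exactly the shape [read_ct_table()] reads. The per-sample truth
#' (positivity, class labels, drawn fractions) is attached as
#' `attr(x, "truth")` for parameter-recovery tests. Deterministic for a
#' fixed seed.
#'
#' @param spec A [qpcr_cohort_spec()].
#' @return Data frame `sample_id`, `assay`, `ct`, `replicate` with a
#'   `truth` attribute.
#' @export
gen_qpcr_cohort <- function(spec) {
  stopifnot(inherits(spec, "qpcr_cohort_spec"))
  validate_qpcr_spec(spec)
  ct_cols <- data.frame(sample_id = character(), assay = character(),
                        ct = numeric(), replicate = integer(),
                        stringsAsFactors = FALSE)
  if (spec$n_samples == 0L) {
    attr(ct_cols, "truth") <- data.frame(sample_id = character(),
                                         positive = logical(),
                                         nkp44_class = character(),
                                         nkp30_class = character(),
                                         stringsAsFactors = FALSE)
    return(ct_cols)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  rows <- list(); truth <- list()
  # fixed draw order per sample: positivity, nkp44 class, nkp44 fractions,
  # nkp30 class, nkp30 fractions, ACTB Ct, expression offsets, well noise
  for (i in seq_len(spec$n_samples)) {
    sid <- sprintf("S%03d", i)
    positive <- stats::runif(1) < spec$positivity_rate
    dom <- stats::runif(1) < spec$p_dominant
    f44 <- draw_fraction_nkp44(
      if (dom) spec$dirichlet_dominant else spec$dirichlet_nondominant,
      dom, band = spec$boundary_band)
    ab <- stats::runif(1) < spec$p_ab
    f30 <- draw_fraction_nkp30(
      if (ab) spec$dirichlet_ab else spec$dirichlet_c,
      ab, band = spec$boundary_band)
    actb <- stats::rnorm(1, spec$ct_reference_mean, spec$ct_reference_sd)
    # total receptor expression relative to ACTB: 2^-delta, delta ~ N(6, 1)
    delta44 <- stats::rnorm(1, 6, 1)
    delta30 <- stats::rnorm(1, 6, 1)

    emit <- function(assay, ct) {
      noise <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, assay = assay,
        ct = if (is.na(ct)) NA_real_ else ct + noise,
        replicate = 1L, stringsAsFactors = FALSE)
    }
    emit("ACTB", actb)
    emit("NKP46", actb + stats::rnorm(1, 7, 1))
    if (positive) {
      e44 <- 2^-delta44; e30 <- 2^-delta30
      emit("NKP44_TOTAL", actb + delta44)
      for (k in 1:3) emit(RECEPTOR_VARIANTS$NKP44[k], actb - log2(e44 * f44[k]))
      emit("NKP30_TOTAL", actb + delta30)
      for (k in 1:3) emit(RECEPTOR_VARIANTS$NKP30[k], actb - log2(e30 * f30[k]))
    } else {
      for (a in c("NKP44_TOTAL", RECEPTOR_VARIANTS$NKP44,
                  "NKP30_TOTAL", RECEPTOR_VARIANTS$NKP30)) emit(a, NA_real_)
    }
    truth[[i]] <- data.frame(
      sample_id = sid, positive = positive,
      nkp44_class = if (!positive) "NEGATIVE"
                    else if (dom) "NKP44_1_DOMINANT" else "NKP44_2_3",
      nkp30_class = if (!positive) "NEGATIVE"
                    else if (ab) "NKP30_AB" else "NKP30_C",
      f44_1 = f44[1L], f30_a = f30[1L], f30_c = f30[3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Specification of a synthetic TCGA-style cohort
#'
#' Each patient contributes a primary-solid-tumor (01) sample and, with
#' probability `matched_fraction`, a solid-tissue-normal (11) sample. The
#' normal sample's NKp30 category is drawn from `stn_profile_mix` over
#' `{AB, C, NEGATIVE}`; the tumor category copies it, except with
#' probability `shift_probability` it is resampled independently from
#' `pst_profile_mix` (unmatched tumors always draw from `pst_profile_mix`).
#' NKp44 positivity is Bernoulli per sample class
#' (`nkp44_positive_rate_pst` / `_stn`), and positive NKp44 samples are
#' dominant with `nkp44_p_dominant`.
#'
#' @param n_patients Number of patients.
#' @param matched_fraction Probability a patient has an STN sample.
#' @param cancer_acronym TCGA study code (validated against the cluster map).
#' @param stn_profile_mix,pst_profile_mix Named probability vectors over
#'   `c(AB =, C =, NEGATIVE =)`, each summing to 1.
#' @param shift_probability Probability the tumor NKp30 category is
#'   resampled independently of the matched normal.
#' @param nkp44_positive_rate_pst,nkp44_positive_rate_stn NKp44 positivity
#'   rates (defaults 0.15 and 0.05: tumor incidence in the 10-20% range,
#'   lower in normal tissue).
#' @param nkp44_p_dominant Probability a positive NKp44 sample is dominant
#'   (default 0.9: dominant profiles in the 80-100% range).
#' @param boundary_band Decision-boundary exclusion band (percentage
#'   points), as in [qpcr_cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A list of class `tcga_cohort_spec`.
#' @export
tcga_cohort_spec <- function(n_patients = 50, matched_fraction = 0.3,
                             cancer_acronym = "BRCA",
                             stn_profile_mix = c(AB = 0.59, C = 0.40,
                                                 NEGATIVE = 0.01),
                             pst_profile_mix = c(AB = 0.59, C = 0.40,
                                                 NEGATIVE = 0.01),
                             shift_probability = 0.5,
                             nkp44_positive_rate_pst = 0.15,
                             nkp44_positive_rate_stn = 0.05,
                             nkp44_p_dominant = 0.9,
                             boundary_band = 1, seed = 1L) {
  spec <- list(n_patients = n_patients, matched_fraction = matched_fraction,
               cancer_acronym = cancer_acronym,
               stn_profile_mix = stn_profile_mix,
               pst_profile_mix = pst_profile_mix,
               shift_probability = shift_probability,
               nkp44_positive_rate_pst = nkp44_positive_rate_pst,
               nkp44_positive_rate_stn = nkp44_positive_rate_stn,
               nkp44_p_dominant = nkp44_p_dominant,
               boundary_band = boundary_band, seed = as.integer(seed))
  validate_tcga_spec(spec)
  structure(spec, class = "tcga_cohort_spec")
}

validate_tcga_spec <- function(s) {
  stopifnot(s$n_patients >= 0,
            s$matched_fraction >= 0, s$matched_fraction <= 1,
            s$shift_probability >= 0, s$shift_probability <= 1,
            s$nkp44_positive_rate_pst >= 0, s$nkp44_positive_rate_pst <= 1,
            s$nkp44_positive_rate_stn >= 0, s$nkp44_positive_rate_stn <= 1,
            s$nkp44_p_dominant >= 0, s$nkp44_p_dominant <= 1,
            s$boundary_band >= 0)
  for (mix in list(s$stn_profile_mix, s$pst_profile_mix)) {
    if (!setequal(names(mix), c("AB", "C", "NEGATIVE")) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      stop("profile mixes must be probabilities over {AB, C, NEGATIVE} summing to 1",
           call. = FALSE)
    }
  }
  assign_cluster(s$cancer_acronym) # errors on unknown acronyms
  invisible(s)
}

# Write one sample's RSEM isoform and gene files; NKp30/NKp44 categories
# decide the counts. Returns the two relative paths.
write_rsem_sample <- function(dir, barcode, nkp30_cat, nkp44_positive,
                              nkp44_dominant, spec) {
  vm <- synthetic_variant_map()
  iso <- data.frame(isoform_id = vm$isoform_id,
                    normalized_count = 0, stringsAsFactors = FALSE)
  scale30 <- exp(stats::rnorm(1, log(200), 0.5))
  scale44 <- exp(stats::rnorm(1, log(50), 0.5))
  if (nkp30_cat != "NEGATIVE") {
    f30 <- draw_fraction_nkp30(
      if (nkp30_cat == "AB") c(10, 4, 4) else c(4, 4, 10),
      nkp30_cat == "AB", band = spec$boundary_band)
    iso$normalized_count[4:6] <- scale30 * f30
  }
  if (nkp44_positive) {
    f44 <- draw_fraction_nkp44(
      if (nkp44_dominant) c(16, 2, 2) else c(4, 8, 8),
      nkp44_dominant, band = spec$boundary_band)
    iso$normalized_count[1:3] <- scale44 * f44
  }
  gene <- data.frame(
    gene_id = unname(synthetic_gene_ids[c("NKP44", "NKP30", "NKP46")]),
    normalized_count = c(sum(iso$normalized_count[1:3]),
                         sum(iso$normalized_count[4:6]),
                         exp(stats::rnorm(1, log(300), 0.5))),
    stringsAsFactors = FALSE)
  iso_rel <- paste0(barcode, ".rsem.isoforms.normalized_results.tsv")
  gene_rel <- paste0(barcode, ".rsem.gene.normalized_results.tsv")
  utils::write.table(
    data.frame(isoform_id = iso$isoform_id,
               normalized_count = sprintf("%.6f", iso$normalized_count)),
    file.path(dir, iso_rel), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = gene$gene_id,
               normalized_count = sprintf("%.6f", gene$normalized_count)),
    file.path(dir, gene_rel), sep = "\t", quote = FALSE, row.names = FALSE)
  c(iso_rel, gene_rel)
}

#' Generate a synthetic TCGA-style cohort on disk
#'
#' Writes per-sample RSEM-style isoform and gene files plus a manifest TSV
#' (`barcode`, `cancer_acronym`, `isoform_path`, `gene_path`) into `dir`,
#' using valid barcodes (`TCGA-SY-<patient>-01A-01T-<plate>-07` /
#' `...-11A-...`). Deterministic for a fixed seed. The per-patient truth is
#' attached to the returned manifest as `attr(x, "truth")`.
#'
#' @param spec A [tcga_cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame (paths relative to `dir`), invisibly
#'   also written to `file.path(dir, "manifest.tsv")`.
#' @export
gen_tcga_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "tcga_cohort_spec"))
  validate_tcga_spec(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  cats <- c("AB", "C", "NEGATIVE")
  draw_cat <- function(mix) sample(cats, 1L, prob = mix[cats])
  man <- list(); truth <- list()
  for (i in seq_len(spec$n_patients)) {
    patient <- sprintf("TCGA-SY-%04d", i)
    matched <- stats::runif(1) < spec$matched_fraction
    stn_cat <- draw_cat(spec$stn_profile_mix)
    shifted <- stats::runif(1) < spec$shift_probability
    pst_cat <- if (matched && !shifted) stn_cat
               else draw_cat(spec$pst_profile_mix)
    pst44_pos <- stats::runif(1) < spec$nkp44_positive_rate_pst
    stn44_pos <- stats::runif(1) < spec$nkp44_positive_rate_stn
    pst44_dom <- stats::runif(1) < spec$nkp44_p_dominant
    stn44_dom <- stats::runif(1) < spec$nkp44_p_dominant

    pst_bc <- sprintf("%s-01A-01T-%04d-07", patient, i)
    paths <- write_rsem_sample(dir, pst_bc, pst_cat, pst44_pos, pst44_dom, spec)
    man[[length(man) + 1L]] <- data.frame(
      barcode = pst_bc, cancer_acronym = spec$cancer_acronym,
      isoform_path = paths[1L], gene_path = paths[2L],
      stringsAsFactors = FALSE)
    if (matched) {
      stn_bc <- sprintf("%s-11A-01T-%04d-07", patient, i)
      paths <- write_rsem_sample(dir, stn_bc, stn_cat, stn44_pos, stn44_dom,
                                 spec)
      man[[length(man) + 1L]] <- data.frame(
        barcode = stn_bc, cancer_acronym = spec$cancer_acronym,
        isoform_path = paths[1L], gene_path = paths[2L],
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      patient_id = patient, matched = matched,
      stn_cat = if (matched) stn_cat else NA_character_,
      pst_cat = pst_cat, shifted = shifted,
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(barcode = character(), cancer_acronym = character(),
               isoform_path = character(), gene_path = character(),
               stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(manifest, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), matched = logical(),
               stn_cat = character(), pst_cat = character(),
               shifted = logical(), stringsAsFactors = FALSE)
  manifest
}
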