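# qPCR quantification: Ct tables -> relative expression -> variant
# percentage profiles with positivity calls.

#' Relative expression by the 2^-dCt method
#'
#' Computes \eqn{2^{-(Ct_{target} - Ct_{reference})}}, the standard relative
#' expression of a target gene against a reference gene measured in the same
#' sample. An undetected well (represented as `NA`) propagates to an undefined
#' expression value (`NA`), never to zero.
#'
#' @param ct_target Cycle-threshold of the target assay (cycles), or `NA` if
#'   undetected.
#' @param ct_reference Cycle-threshold of the reference assay, or `NA`.
#' @return Relative expression (dimensionless, positive), vectorised; `NA`
#'   where either input is undetected.
#' @export
#' @examples
#' relative_expression(25, 20) # 2^-5 = 0.03125
#' relative_expression(18, 21) # 2^3  = 8
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(is.numeric(ct_target) || all(is.na(ct_target)),
            is.numeric(ct_reference) || all(is.na(ct_reference)))
  bad <- !is.na(ct_target) & (!is.finite(ct_target) | ct_target <= 0)
  bad_r <- !is.na(ct_reference) & (!is.finite(ct_reference) | ct_reference <= 0)
  if (any(bad) || any(bad_r)) {
    stop("Ct values must be positive and finite (use NA for undetected wells)",
         call. = FALSE)
  }
  2^-(as.numeric(ct_target) - as.numeric(ct_reference))
}

#' Aggregate replicate wells for one sample and assay
#'
#' Replicate Ct values are averaged arithmetically over the detected wells;
#' a partially detected replicate set counts as detected. Only if every
#' replicate is undetected is the aggregate undetected (`NA`).
#'
#' @param ct Numeric vector of replicate Ct values; `NA` marks undetected
#'   wells. Must be non-empty.
#' @return A single Ct value, or `NA` if all replicates were undetected.
#' @export
aggregate_replicates <- function(ct) {
  if (length(ct) == 0L) stop("no replicate Ct values supplied", call. = FALSE)
  det <- ct[!is.na(ct)]
  if (length(det) == 0L) return(NA_real_)
  mean(det)
}

#' Call mRNA positivity from the receptor-total qPCR assay
#'
#' A sample is positive for a receptor when the receptor-total assay
#' (NKp44-total or NKp30-total) yields a detected aggregated Ct at or below
#' `max_cycles`. The boundary is inclusive: a Ct exactly at `max_cycles`
#' is positive. A missing or fully undetected total assay gives a negative
#' call.
#'
#' @param ct_total Aggregated Ct of the receptor-total assay (`NA` if
#'   undetected or the assay is absent).
#' @param max_cycles Detection cutoff in cycles (default 40).
#' @return Logical positivity call, vectorised.
#' @export
call_positivity_qpcr <- function(ct_total, max_cycles = 40) {
  stopifnot(is.numeric(max_cycles), length(max_cycles) == 1L, max_cycles > 0)
  !is.na(ct_total) & ct_total <= max_cycles
}

#' Variant percentages from relative expressions
#'
#' Converts the relative expressions of a receptor's splice variants into a
#' percentage composition: \eqn{100 \cdot e_i / \sum_j e_j}. The denominator
#' is the sum of the variant expressions (not the receptor-total assay), so
#' the percentages always form a well-defined composition summing to 100.
#' The result is scale-invariant: multiplying every expression by a positive
#' constant leaves the percentages unchanged.
#'
#' @param exprs Named numeric vector of variant relative expressions
#'   (non-negative; `NA` = undefined).
#' @return Named numeric vector of percentages summing to 100, or a vector of
#'   `NA`s (same names) when the profile is undefined: any expression
#'   undefined, or all expressions zero.
#' @export
#' @examples
#' variant_percentages(c(v1 = 0.5, v2 = 0.25, v3 = 0.25))
variant_percentages <- function(exprs) {
  stopifnot(is.numeric(exprs), length(exprs) >= 2L)
  if (any(!is.na(exprs) & exprs < 0)) {
    stop("relative expressions must be non-negative", call. = FALSE)
  }
  if (anyNA(exprs) || sum(exprs) <= 0) {
    out <- rep(NA_real_, length(exprs))
    names(out) <- names(exprs)
    return(out)
  }
  100 * exprs / sum(exprs)
}

#' Read a qPCR Ct table
#'
#' Reads a CSV or TSV file with header columns `sample_id`, `assay`, `ct`,
#' `replicate`. An empty `ct` field or the value `"Undetermined"`
#' (case-insensitive) marks an undetected well. Assay names are matched
#' case-insensitively against the panel
#' (NKp44-total/-1/-2/-3, NKp30-total/-a/-b/-c, NKp46, ACTB).
#'
#' @param path Path to the table; the delimiter is inferred from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A data frame with columns `sample_id`, `assay` (canonical),
#'   `ct` (numeric, `NA` = undetected), `replicate` (integer).
#' @export
read_ct_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("sample_id", "assay", "ct", "replicate")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ct_chr <- trimws(raw$ct)
  undet <- ct_chr == "" | toupper(ct_chr) %in% c("UNDETERMINED", "NA")
  ct <- suppressWarnings(as.numeric(ct_chr))
  if (any(!undet & is.na(ct))) {
    stop("non-numeric Ct values: ",
         paste(unique(ct_chr[!undet & is.na(ct)]), collapse = ", "),
         call. = FALSE)
  }
  ct[undet] <- NA_real_
  data.frame(
    sample_id = raw$sample_id,
    assay = normalize_assay(raw$assay),
    ct = ct,
    replicate = as.integer(raw$replicate),
    stringsAsFactors = FALSE
  )
}

# Aggregate a long Ct table over replicates -> one row per sample x assay.
# The "\r" key separator cannot occur in sample ids read from a delimited file.
aggregate_ct_table <- function(ct_table) {
  key <- paste(ct_table$sample_id, ct_table$assay, sep = "\r")
  agg <- vapply(split(ct_table$ct, key), aggregate_replicates, numeric(1))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    sample_id = vapply(parts, `[[`, character(1), 1L),
    assay = vapply(parts, `[[`, character(1), 2L),
    ct = unname(agg),
    stringsAsFactors = FALSE
  )
}

#' Build per-sample variant percentage profiles from a Ct table
#'
#' The full qPCR quantification step: replicates are aggregated (mean of
#' detected wells), positivity is called from each receptor-total assay,
#' and for positive samples the splice-variant percentages are computed
#' from the variant assays' \eqn{2^{-\Delta Ct}} expressions (normalised to
#' beta-actin; the reference cancels in the composition). Samples without a
#' detected ACTB measurement are excluded with a warning. As a side output,
#' beta-actin-normalised expressions of the receptor-total and NKp46 assays
#' are returned for expression-level comparisons.
#'
#' @param ct_table Data frame as returned by [read_ct_table()] (columns
#'   `sample_id`, `assay`, `ct`, `replicate`; `replicate` optional).
#' @param max_cycles Positivity cutoff in cycles, see [call_positivity_qpcr()].
#' @return An object of class `qpcr_profiles`: a list with
#'   \describe{
#'     \item{profiles}{data frame `sample_id`, `receptor`, `positive`,
#'       `pct_v1`, `pct_v2`, `pct_v3` (NKp44-1/2/3 or NKp30a/b/c order).}
#'     \item{totals}{data frame `sample_id`, `assay`, `rel_expr` of
#'       beta-actin-normalised NKp44-total, NKp30-total and NKp46.}
#'     \item{excluded}{character vector of samples dropped for missing ACTB.}
#'   }
#' @export
build_qpcr_profiles <- function(ct_table, max_cycles = 40) {
  stopifnot(is.data.frame(ct_table))
  empty_profiles <- data.frame(
    sample_id = character(), receptor = character(), positive = logical(),
    pct_v1 = numeric(), pct_v2 = numeric(), pct_v3 = numeric(),
    stringsAsFactors = FALSE
  )
  empty_totals <- data.frame(sample_id = character(), assay = character(),
                             rel_expr = numeric(), stringsAsFactors = FALSE)
  if (nrow(ct_table) == 0L) {
    return(structure(list(profiles = empty_profiles, totals = empty_totals,
                          excluded = character()),
                     class = "qpcr_profiles"))
  }
  agg <- aggregate_ct_table(ct_table)
  samples <- unique(ct_table$sample_id)

  ct_of <- function(sid, assay) {
    hit <- agg$ct[agg$sample_id == sid & agg$assay == assay]
    if (length(hit) == 0L) NA_real_ else hit[[1L]]
  }

  excluded <- character()
  prof_rows <- list()
  tot_rows <- list()
  for (sid in samples) {
    actb <- ct_of(sid, "ACTB")
    if (is.na(actb)) {
      excluded <- c(excluded, sid)
      next
    }
    for (a in c("NKP44_TOTAL", "NKP30_TOTAL", "NKP46")) {
      ct_a <- ct_of(sid, a)
      tot_rows[[length(tot_rows) + 1L]] <- data.frame(
        sample_id = sid, assay = a,
        rel_expr = if (is.na(ct_a)) NA_real_ else relative_expression(ct_a, actb),
        stringsAsFactors = FALSE
      )
    }
    for (rec in RECEPTORS) {
      positive <- call_positivity_qpcr(ct_of(sid, RECEPTOR_TOTALS[[rec]]),
                                       max_cycles)
      pct <- rep(NA_real_, 3L)
      if (positive) {
        vr <- RECEPTOR_VARIANTS[[rec]]
        ct_v <- vapply(vr, function(a) ct_of(sid, a), numeric(1))
        ex <- ifelse(is.na(ct_v), NA_real_,
                     relative_expression(ct_v, actb))
        pct <- unname(variant_percentages(ex))
      }
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        sample_id = sid, receptor = rec, positive = positive,
        pct_v1 = pct[1L], pct_v2 = pct[2L], pct_v3 = pct[3L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(excluded)) {
    warning("excluded sample(s) with no detected ACTB: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      profiles = if (length(prof_rows)) do.call(rbind, prof_rows) else empty_profiles,
      totals = if (length(tot_rows)) do.call(rbind, tot_rows) else empty_totals,
      excluded = excluded
    ),
    class = "qpcr_profiles"
  )
}

#' @export
print.qpcr_profiles <- function(x, ...) {
  n <- length(unique(x$profiles$sample_id))
  cat("qPCR variant profiles:", n, "sample(s)\n")
  for (rec in RECEPTORS) {
    p <- x$profiles[x$profiles$receptor == rec, ]
    cat(sprintf("  %s: %d/%d positive\n", rec, sum(p$positive), nrow(p)))
  }
  if (length(x$excluded)) {
    cat("  excluded (no ACTB):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
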