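# Threshold classification of splice-variant profiles and matched-pair
# shift typing.

#' Classifier configuration
#'
#' @param nkp44_dominance_threshold Percent of NKp44-1 among NKp44
#'   transcripts at or above which a sample is NKp44-1-dominant (inhibitory
#'   profile). Default 66.
#' @param nkp44_boundary_inclusive Whether a sample exactly at the threshold
#'   is dominant. Default `TRUE` (the rule is "NKp44-1 >= 66%").
#' @param nkp30_tie_to_ab Whether `%NKp30a == %NKp30c` is called NKp30a/b.
#'   Default `TRUE` (the rule is "%NKp30a >= %NKp30c").
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(nkp44_dominance_threshold = 66,
                              nkp44_boundary_inclusive = TRUE,
                              nkp30_tie_to_ab = TRUE) {
  stopifnot(is.numeric(nkp44_dominance_threshold),
            length(nkp44_dominance_threshold) == 1L,
            nkp44_dominance_threshold > 0, nkp44_dominance_threshold < 100,
            is.logical(nkp44_boundary_inclusive),
            is.logical(nkp30_tie_to_ab))
  structure(list(nkp44_dominance_threshold = nkp44_dominance_threshold,
                 nkp44_boundary_inclusive = nkp44_boundary_inclusive,
                 nkp30_tie_to_ab = nkp30_tie_to_ab),
            class = "classifier_config")
}

check_percent <- function(p, what) {
  bad <- !is.na(p) & (p < 0 | p > 100)
  if (any(bad)) {
    stop(what, " outside [0, 100]: ", paste(p[bad], collapse = ", "),
         call. = FALSE)
  }
}

#' Classify the NKp44 splice-variant profile of a sample
#'
#' A positive sample is `NKP44_1_DOMINANT` (inhibitory profile) when NKp44-1
#' accounts for at least the dominance threshold (default 66%) of NKp44
#' transcripts, and `NKP44_2_3` (activating profile) otherwise. Negative
#' samples, and positive samples whose percentages are undefined, are
#' `NEGATIVE`.
#'
#' @param percent_nkp44_1 Percent of NKp44-1 among the three variants
#'   (vectorised; `NA` = undefined).
#' @param positive Logical positivity call(s).
#' @param config A [classifier_config()].
#' @return Character vector over
#'   `{"NEGATIVE", "NKP44_1_DOMINANT", "NKP44_2_3"}`.
#' @export
#' @examples
#' classify_nkp44(c(85, 50), positive = c(TRUE, TRUE))
classify_nkp44 <- function(percent_nkp44_1, positive,
                           config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"), is.logical(positive))
  check_percent(percent_nkp44_1, "percent_nkp44_1")
  thr <- config$nkp44_dominance_threshold
  dominant <- if (config$nkp44_boundary_inclusive) {
    percent_nkp44_1 >= thr
  } else {
    percent_nkp44_1 > thr
  }
  out <- ifelse(dominant, "NKP44_1_DOMINANT", "NKP44_2_3")
  out[!positive | is.na(percent_nkp44_1)] <- "NEGATIVE"
  out
}

#' Classify the NKp30 splice-variant profile of a sample
#'
#' A positive sample is `NKP30_AB` (activating profile) when
#' `%NKp30a >= %NKp30c` and `NKP30_C` (inhibitory) otherwise; the NKp30b
#' percentage never enters the rule. Negative samples, and samples with
#' undefined percentages, are `NEGATIVE`.
#'
#' @param percent_a,percent_c Percentages of NKp30a and NKp30c (vectorised).
#' @param positive Logical positivity call(s).
#' @param config A [classifier_config()].
#' @return Character vector over `{"NEGATIVE", "NKP30_AB", "NKP30_C"}`.
#' @export
classify_nkp30 <- function(percent_a, percent_c, positive,
                           config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"), is.logical(positive))
  check_percent(percent_a, "percent_a")
  check_percent(percent_c, "percent_c")
  ab <- if (config$nkp30_tie_to_ab) percent_a >= percent_c
        else percent_a > percent_c
  out <- ifelse(ab, "NKP30_AB", "NKP30_C")
  out[!positive | is.na(percent_a) | is.na(percent_c)] <- "NEGATIVE"
  out
}

#' Classify every row of a profiles table
#'
#' Applies the receptor-appropriate rule ([classify_nkp44()] or
#' [classify_nkp30()]) to each row of a profiles data frame as produced by
#' [build_qpcr_profiles()] or [build_tcga_profiles()].
#'
#' @param profiles Data frame with columns `receptor`, `positive`,
#'   `pct_v1`..`pct_v3` (variant order NKp44-1/2/3 or NKp30a/b/c).
#' @param config A [classifier_config()].
#' @return Character vector of profile labels, one per row.
#' @export
classify_profiles <- function(profiles, config = classifier_config()) {
  out <- character(nrow(profiles))
  i44 <- profiles$receptor == "NKP44"
  i30 <- profiles$receptor == "NKP30"
  out[i44] <- classify_nkp44(profiles$pct_v1[i44], profiles$positive[i44],
                             config)
  out[i30] <- classify_nkp30(profiles$pct_v1[i30], profiles$pct_v3[i30],
                             profiles$positive[i30], config)
  out
}

#' Type the profile shift between matched normal and tumor samples
#'
#' Compares one patient's profile call in the solid-tissue-normal (STN)
#' sample against the matched primary-solid-tumor (PST) sample. When both
#' calls are defined (non-negative), the pair is `IDENTICAL` or
#' `NON_IDENTICAL`, with the direction of an NKp30 shift labelled
#' `AB_TO_C` or `C_TO_AB` (identical pairs have direction `NONE`). A pair
#' with a receptor-negative sample on either side is non-defined: it is
#' excluded from the identical/non-identical tally (`identity` is `NA`) and
#' its direction is `NON_DEFINED`.
#'
#' @param stn_call,pst_call Profile labels from [classify_nkp30()] (or
#'   [classify_nkp44()]), vectorised.
#' @return Data frame `stn_call`, `pst_call`, `identity`
#'   (`"IDENTICAL"`/`"NON_IDENTICAL"`/`NA`), `direction`
#'   (`"AB_TO_C"`, `"C_TO_AB"`, `"NONE"`, `"NON_DEFINED"`).
#' @export
classify_shift <- function(stn_call, pst_call) {
  labels44 <- c("NKP44_1_DOMINANT", "NKP44_2_3")
  labels30 <- c("NKP30_AB", "NKP30_C")
  known <- c("NEGATIVE", labels44, labels30)
  stopifnot(all(stn_call %in% known), all(pst_call %in% known),
            length(stn_call) == length(pst_call))
  rec_of <- function(l) ifelse(l %in% labels44, "NKP44",
                        ifelse(l %in% labels30, "NKP30", NA_character_))
  r_stn <- rec_of(stn_call); r_pst <- rec_of(pst_call)
  mism <- !is.na(r_stn) & !is.na(r_pst) & r_stn != r_pst
  if (any(mism)) {
    stop("receptor mismatch between STN and PST calls", call. = FALSE)
  }
  neg <- stn_call == "NEGATIVE" | pst_call == "NEGATIVE"
  identity <- ifelse(neg, NA_character_,
                     ifelse(stn_call == pst_call, "IDENTICAL",
                            "NON_IDENTICAL"))
  direction <- rep("NONE", length(stn_call))
  direction[stn_call == "NKP30_AB" & pst_call == "NKP30_C"] <- "AB_TO_C"
  direction[stn_call == "NKP30_C" & pst_call == "NKP30_AB"] <- "C_TO_AB"
  direction[neg] <- "NON_DEFINED"
  data.frame(stn_call = stn_call, pst_call = pst_call,
             identity = identity, direction = direction,
             stringsAsFactors = FALSE)
}
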